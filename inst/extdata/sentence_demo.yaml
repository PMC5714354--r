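# Six-node sentence-parsing network for "I hit the thief with the club".
# Connection gains are synthetic calibration artifacts, hand-tuned with
# scripts/calibrate_network.R to reproduce the qualitative parsing outcomes;
# they are not measured quantities.
nodes:
  - {name: I,         module: S}
  - {name: hit,       module: V}
  - {name: the_thief, module: O}
  - {name: with_vmod, module: V-mod}
  - {name: with_omod, module: O-mod}
  - {name: the_club,  module: O}
edges:
  - {from: I,         to: hit,       sign: excitatory, gain: 20}
  - {from: hit,       to: the_thief, sign: excitatory, gain: 20}
  - {from: hit,       to: with_vmod, sign: excitatory, gain: 20}
  - {from: the_thief, to: with_omod, sign: excitatory, gain: 20}
  - {from: with_vmod, to: the_club,  sign: excitatory, gain: 20}
  - {from: with_omod, to: the_club,  sign: excitatory, gain: 20}
  # asymmetric mutual inhibition between the competing modifiers
  - {from: with_vmod, to: with_omod, sign: inhibitory, gain: 30}
  - {from: with_omod, to: with_vmod, sign: inhibitory, gain: 5}
context:
  high: {target: with_vmod, offset: 50, sd: 5}
  low:  {target: with_vmod, offset: 5,  sd: 0.5}
schedule:
  - {node: I,         onset: 1.0, duration: 1.2, intensity: 120}
  - {node: hit,       onset: 2.5, duration: 1.2, intensity: 60}
  - {node: the_thief, onset: 4.0, duration: 1.2, intensity: 60}
  - {node: with_vmod, onset: 5.5, duration: 1.2, intensity: 60}
  - {node: with_omod, onset: 5.5, duration: 1.2, intensity: 60}
  - {node: the_club,  onset: 7.0, duration: 1.2, intensity: 60}
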