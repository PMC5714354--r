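#!/usr/bin/env Rscript
# Calibration sweep for the sentence-demo connection gains.
#
# The demo's inter-node weights are calibration artifacts: this script
# documents how they were chosen.  It sweeps the pre-activation gain, the
# asymmetric mutual-inhibition gains of the two modifier modules, and the
# contextual offset, and reports which combinations reproduce the intended
# qualitative outcomes:
#   * context high  -> object-modifier interpretation (exclusive winner)
#   * context low   -> verb-modifier interpretation (exclusive winner)
#   * Hi = 23/24 mV -> defective trace or memory loss in both contexts
# The shipped inst/extdata/sentence_demo.yaml uses one passing combination.

suppressPackageStartupMessages(library(cmcircuit))

score_config <- function(pre_gain, inh_vo, inh_ov, ctx_offset, seed = 1) {
  demo <- sentence_demo("high")
  e <- demo$spec$edges
  e$gain[e$sign == "excitatory"] <- pre_gain
  e$gain[e$from == "with_vmod" & e$to == "with_omod"] <- inh_vo
  e$gain[e$from == "with_omod" & e$to == "with_vmod"] <- inh_ov
  demo$spec$edges <- e

  run <- function(ctx_off, ctx_sd, seed) {
    sp <- demo$spec
    sp$context <- data.frame(target = "with_vmod", offset = ctx_off,
                             sd = ctx_sd)
    simulate_network(sp, demo$schedule, seed = seed)
  }
  hi <- run(ctx_offset, 0.1 * ctx_offset, seed)
  lo <- run(5, 0.5, seed)
  sp23 <- demo$spec
  sp23$context <- data.frame(target = "with_vmod", offset = ctx_offset,
                             sd = 0.1 * ctx_offset)
  pert <- balance_perturbation(sp23, demo$schedule, c(23, 24), seed = seed)
  ok <- hi$outcome == "interpretation_A" &&
    lo$outcome == "interpretation_B" &&
    all(vapply(pert, function(x)
      x$outcome %in% c("defective", "memory_loss"), logical(1)))
  data.frame(pre_gain = pre_gain, inh_vo = inh_vo, inh_ov = inh_ov,
             ctx_offset = ctx_offset, high = hi$outcome, low = lo$outcome,
             Hi23 = pert[["23"]]$outcome, Hi24 = pert[["24"]]$outcome,
             pass = ok)
}

grid <- expand.grid(pre_gain = c(15, 20, 25),
                    inh_vo = c(20, 30),
                    inh_ov = c(2, 5),
                    ctx_offset = c(40, 50, 60))
res <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i)
  do.call(score_config, as.list(grid[i, ]))))
print(res)
cat(sprintf("\n%d of %d combinations pass; shipped config uses pre_gain=20, ",
            sum(res$pass), nrow(res)),
    "inh_vo=30, inh_ov=5, ctx_offset=50\n")
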