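# Builders for small hand-specified cohorts and a cached calibrated
# generator config (calibration is deterministic; cache it once per run).

make_cohort <- function(sweh, ri, ct, um = 0, hy = 0, lfh = 0, pi = 0, pv = 0,
                        malignant = NULL) {
  n <- max(lengths(list(sweh, ri, ct, um, hy, lfh, pi, pv,
                        if (is.null(malignant)) 0 else malignant)))
  df <- data.frame(
    node_id = sprintf("N%03d", seq_len(n)),
    patient_id = sprintf("P%03d", seq_len(n)),
    swe_hardness_kpa = rep_len(sweh, n),
    roundness_index = rep_len(ri, n),
    cortical_thickness_mm = rep_len(ct, n),
    indefinite_margins = rep_len(um, n),
    hypoechogenicity = rep_len(hy, n),
    loss_fatty_hilum = rep_len(lfh, n),
    peripheral_infiltration = rep_len(pi, n),
    peripheral_vascularization = rep_len(pv, n)
  )
  if (!is.null(malignant)) df$malignant <- rep_len(malignant, n)
  df
}

# Cohort realizing a given binary feature vector exactly under Model B cuts
# (137 / -2.25 / 3.50): used for exhaustive enumeration through the record
# interface.
cohort_from_binary <- function(bin) {
  make_cohort(
    sweh = ifelse(bin$b_sweh == 1, 150, 120),
    ri = ifelse(bin$b_ri == 1, 1.3, 2.5),
    ct = ifelse(bin$b_ct == 1, 5, 1),
    um = bin$um, hy = bin$hy, lfh = bin$lfh, pi = bin$pi, pv = bin$pv
  )
}

cached_default_cfg <- local({
  cfg <- NULL
  function() {
    if (is.null(cfg)) cfg <<- calibrate_latent(generator_config())
    cfg
  }
})

# All-pairs AUC oracle: P(malignant score > benign score) + half-ties.
auc_all_pairs <- function(score, label) {
  s1 <- score[label == 1]
  s0 <- score[label == 0]
  cmp <- outer(s1, s0, ">") + 0.5 * outer(s1, s0, "==")
  mean(cmp)
}
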