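# Small in-code builders for raw assay tables.

make_western <- function(ratios, wt_norm = 2, batches = NULL) {
  # one replicate per batch; `ratios` are the target variant/WT
  # loading-normalized ratios per batch
  if (is.null(batches)) batches <- paste0("B", seq_along(ratios))
  list(
    variant = data.frame(batch_id = batches,
                         band_intensity = 100 * ratios * wt_norm,
                         loading_control_intensity = 100),
    wt = data.frame(batch_id = batches,
                    band_intensity = 100 * wt_norm,
                    loading_control_intensity = 100)
  )
}

make_wells <- function(effector_rlu, batches = paste0("B", 1:3),
                       empty_firefly = 5000, renilla = 10000,
                       wt_level = 0.2, promoter_only_level = NULL) {
  # effector_rlu: named list mapping effector -> per-batch normalized RLU
  # values (relative to WT); "WT" entry optional and defaults to 1s
  rows <- list(data.frame(construct = "empty_vector", effector = "none",
                          firefly = rep(empty_firefly, length(batches)),
                          renilla = renilla, batch_id = batches))
  if (!is.null(promoter_only_level)) {
    rows <- c(rows, list(data.frame(
      construct = "promoter_only", effector = "WT",
      firefly = empty_firefly * promoter_only_level,
      renilla = renilla, batch_id = batches)))
  }
  if (!"WT" %in% names(effector_rlu)) {
    effector_rlu <- c(list(WT = rep(1, length(batches))), effector_rlu)
  }
  for (e in names(effector_rlu)) {
    rows <- c(rows, list(data.frame(
      construct = "promoter_plus_PBS1", effector = e,
      firefly = empty_firefly * wt_level * effector_rlu[[e]],
      renilla = renilla, batch_id = batches)))
  }
  do.call(rbind, rows)
}

make_migration <- function(vz, iz, cp, n_embryos = 3) {
  data.frame(embryo_id = seq_len(n_embryos),
             vz = rep_len(vz, n_embryos),
             iz = rep_len(iz, n_embryos),
             cp = rep_len(cp, n_embryos))
}

all_category_combinations <- function() {
  expand.grid(expression_category = c("very_low", "low", "normal", "high"),
              repression_status = c("intact", "partial_LOF", "LOF"),
              migration_category = c("cp_low", "cp_mid", "cp_high"),
              stringsAsFactors = FALSE)
}
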