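# Independent oracles used across the suite. These recompute quantities from
# first principles (direct sums, exhaustive enumeration) without touching the
# package's selection or metrics code paths.

# net DALYs of a subset, computed directly from raw fields
oracle_net_dalys <- function(iv, ids, k) {
  sub <- iv[iv$id %in% ids, ]
  sum(sub$dalys_full - sub$cost_full / k)
}

# exhaustive search for the net-DALY-maximising subset under an optional
# budget cap and forced in/out constraints; returns max net and one best set
oracle_best_subset <- function(iv, k, budget = Inf,
                               forced_in = character(),
                               forced_out = character()) {
  iv <- iv[!iv$id %in% forced_out, ]
  n <- nrow(iv)
  stopifnot(n <= 18)
  net_i <- iv$dalys_full - iv$cost_full / k
  best_net <- -Inf; best_ids <- character()
  for (mask in 0:(2^n - 1L)) {
    sel <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1L)))
    if (!all(forced_in %in% iv$id[sel])) next
    if (sum(iv$cost_full[sel]) > budget) next
    net <- sum(net_i[sel])
    if (net > best_net) { best_net <- net; best_ids <- iv$id[sel] }
  }
  list(net = best_net, ids = best_ids)
}

# a tiny hand-buildable intervention table
toy_interventions <- function(df) {
  defaults <- data.frame(cost_saving = FALSE, cases = 1000, level = 1,
                         stringsAsFactors = FALSE)
  for (col in names(defaults))
    if (!col %in% names(df)) df[[col]] <- defaults[[col]]
  if (!"name" %in% names(df)) df$name <- toupper(df$id)
  interventions(df)
}
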