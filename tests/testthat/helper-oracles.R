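# Shared fixtures and independent oracles for the test suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

the_net <- default_network()

# Independent carbon-map application on explicit logical patterns: reads the
# reaction's map table row by row (no bitmask arithmetic).
oracle_apply <- function(net, rxn, patterns, reverse = FALSE) {
  if (is.character(rxn)) rxn <- net$reactions[[rxn]]
  cm <- rxn$carbon_map
  if (reverse)
    cm <- data.frame(sub = cm$prod, sub_c = cm$prod_c,
                     prod = cm$sub, prod_c = cm$sub_c)
  side_out <- if (reverse) rxn$substrates else rxn$products
  out <- lapply(side_out, function(m) logical(net$metabolites[[m]]$n_carbons))
  for (k in seq_len(nrow(cm)))
    out[[cm$prod[k]]][cm$prod_c[k]] <- patterns[[cm$sub[k]]][cm$sub_c[k]]
  out
}

# Closed-form Welch statistics (independent of stats::t.test internals).
welch_oracle <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 /
    (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Exact two-sample permutation p value for the difference of means.
perm_p <- function(x, y) {
  pooled <- c(x, y)
  obs <- abs(mean(x) - mean(y))
  idx <- combn(length(pooled), length(x))
  stats <- apply(idx, 2, function(i)
    abs(mean(pooled[i]) - mean(pooled[-i])))
  mean(stats >= obs - 1e-12)
}

random_simplex <- function(n) { v <- rexp(n); v / sum(v) }

# A small three-sample noise-free peak-area table with known global scale
# factors, built directly (not through generate_experiment).
scaled_table <- function(scales = c(s1 = 1, s2 = 2.5, s3 = 0.4)) {
  base <- list(G6P = c(800, 150, 50), lactate = c(300, 0, 120))
  rows <- list()
  for (s in names(scales)) for (m in names(base)) {
    v <- base[[m]] * scales[[s]]
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = s, group = "g", metabolite = m,
      mass_shift = seq_along(v) - 1L, peak_area = v)
  }
  peak_area_table(do.call(rbind, rows))
}
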