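#' Construct a per-carbon labeling state
#'
#' A label state records, for one molecule of one metabolite, which carbon
#' positions carry the tracer isotope (13C).
#'
#' @param metabolite Metabolite name.
#' @param pattern Logical vector, one flag per carbon position (TRUE =
#'   labeled); or a single number `k` meaning the first `k` of `n` carbons
#'   are labeled when `n` is supplied.
#' @param n Carbon count, required when `pattern` is given as a count.
#' @return Object of class `ppp_state`.
#' @export
label_state <- function(metabolite, pattern, n = NULL) {
  if (is.numeric(pattern) && length(pattern) == 1L && !is.null(n))
    pattern <- seq_len(n) <= pattern
  pattern <- as.logical(pattern)
  if (anyNA(pattern)) stop("pattern must be logical", call. = FALSE)
  structure(list(metabolite = metabolite, pattern = pattern),
            class = "ppp_state")
}

#' Fully labeled / fully unlabeled states for a network metabolite
#' @param net A `ppp_network`.
#' @param metabolite Metabolite name.
#' @return A `ppp_state`.
#' @export
full_state <- function(net, metabolite)
  label_state(metabolite, rep(TRUE, n_carbons(net, metabolite)))

#' @rdname full_state
#' @export
unlabeled_state <- function(net, metabolite)
  label_state(metabolite, rep(FALSE, n_carbons(net, metabolite)))

#' Mass shift (number of labeled carbons) of a label state
#' @param state A `ppp_state`.
#' @return Integer m+k shift.
#' @export
mass_shift <- function(state) sum(state$pattern)

#' @export
print.ppp_state <- function(x, ...) {
  cat(sprintf("%s m+%d [%s]\n", x$metabolite, sum(x$pattern),
              paste(ifelse(x$pattern, "*", "."), collapse = "")))
  invisible(x)
}

# ---- mask-level core -------------------------------------------------------
# A state is an integer bitmask; bit (c-1) set <=> carbon c labeled.

state_to_mask <- function(pattern)
  sum(bitwShiftL(1L, which(pattern) - 1L))

mask_to_pattern <- function(mask, n)
  bitwAnd(bitwShiftR(mask, seq_len(n) - 1L), 1L) == 1L

bitcount <- function(mask, n)
  sum(bitwAnd(bitwShiftR(mask, seq_len(n) - 1L), 1L))

# Apply one reaction at the bitmask level. `direction == "reverse"` reads the
# carbon map backwards (products become substrates).
apply_masks <- function(rxn, masks, direction = "forward") {
  cm <- rxn$carbon_map
  if (direction == "forward") {
    from <- cm$sub; from_c <- cm$sub_c; to <- cm$prod; to_c <- cm$prod_c
    n_out <- length(rxn$products)
  } else {
    from <- cm$prod; from_c <- cm$prod_c; to <- cm$sub; to_c <- cm$sub_c
    n_out <- length(rxn$substrates)
  }
  out <- integer(n_out)
  hit <- bitwAnd(masks[from], bitwShiftL(1L, from_c - 1L)) != 0L
  for (k in which(hit))
    out[to[k]] <- bitwOr(out[to[k]], bitwShiftL(1L, to_c[k] - 1L))
  out
}

resolve_reaction <- function(net, reaction) {
  if (inherits(reaction, "ppp_reaction")) return(reaction)
  rx <- net$reactions[[reaction]]
  if (is.null(rx)) stop("unknown reaction: ", reaction, call. = FALSE)
  rx
}

#' Apply a reaction to explicit label states
#'
#' Propagates per-carbon labels through a reaction's carbon map. In reverse
#' direction the states must match the reaction's products and the reaction
#' must be declared reversible.
#'
#' @param net A `ppp_network`.
#' @param reaction Reaction name or `ppp_reaction`.
#' @param states List of `ppp_state` matching the substrate (or, for
#'   reverse, product) metabolites in order.
#' @param direction `"forward"` or `"reverse"`.
#' @return List of `ppp_state` for the products (or substrates if reverse).
#' @examples
#' net <- default_network()
#' out <- apply_reaction(net, "TKT1",
#'   list(unlabeled_state(net, "Xu5P"), full_state(net, "R5P")))
#' mass_shift(out[[1]])  # sedoheptulose-7P m+5
#' @export
apply_reaction <- function(net, reaction, states,
                           direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  rxn <- resolve_reaction(net, reaction)
  if (direction == "reverse" && !rxn$reversible)
    stop("reaction ", rxn$name, " is irreversible", call. = FALSE)
  side_in <- if (direction == "forward") rxn$substrates else rxn$products
  side_out <- if (direction == "forward") rxn$products else rxn$substrates
  if (length(states) != length(side_in))
    stop(rxn$name, ": expected ", length(side_in), " states, got ",
         length(states), call. = FALSE)
  for (i in seq_along(states)) {
    st <- states[[i]]
    if (!inherits(st, "ppp_state"))
      stop("states must be ppp_state objects", call. = FALSE)
    if (st$metabolite != side_in[i])
      stop(rxn$name, ": state ", i, " is ", st$metabolite, ", expected ",
           side_in[i], call. = FALSE)
    if (length(st$pattern) != n_carbons(net, side_in[i]))
      stop(rxn$name, ": pattern length mismatch for ", st$metabolite,
           call. = FALSE)
  }
  masks <- vapply(states, function(s) state_to_mask(s$pattern), 1L)
  out <- apply_masks(rxn, masks, direction)
  lapply(seq_along(out), function(j)
    label_state(side_out[j],
                mask_to_pattern(out[j], n_carbons(net, side_out[j]))))
}

# ---- cyclic round ----------------------------------------------------------

#' Run one transketolase/transaldolase cyclic-PPP round on six pentoses
#'
#' Six pentose phosphates, taken as two (Xu5P donor, R5P acceptor, Xu5P
#' donor) sets, are recombined into four hexoses (glucose-6P) and two
#' trioses (glyceraldehyde-3P): per set, TKT1 forms S7P + GAP, TAL forms
#' F6P + E4P, TKT2 forms a second F6P + GAP, and the hexoses isomerize to
#' G6P. With `tal_partner_policy = "internal"` the transaldolase triose
#' partner is the GAP just released by TKT1; with `"pool_unlabeled"` it is
#' drawn unlabeled from the cellular triose pool and the TKT1 GAP is emitted
#' to that pool instead (both emitted and consumed pool trioses are reported
#' so label balance can be audited).
#'
#' @param net A `ppp_network`.
#' @param pentose_states List of exactly six 5-carbon `ppp_state`s in set
#'   order (Xu5P, R5P, Xu5P, Xu5P, R5P, Xu5P roles).
#' @param tal_partner_policy `"internal"` or `"pool_unlabeled"`.
#' @return List with `hexoses` (4 G6P states), `trioses` (2 GAP states),
#'   and, under the pool policy, `pool_consumed` and `internal_emitted`
#'   (2 GAP states each).
#' @export
run_cyclic_round <- function(net, pentose_states,
                             tal_partner_policy = c("internal",
                                                    "pool_unlabeled")) {
  tal_partner_policy <- match.arg(tal_partner_policy)
  if (length(pentose_states) != 6L)
    stop("a cyclic round consumes exactly six pentose states", call. = FALSE)
  ok <- vapply(pentose_states, function(s)
    inherits(s, "ppp_state") && length(s$pattern) == 5L, TRUE)
  if (!all(ok))
    stop("all inputs must be 5-carbon label states", call. = FALSE)
  roles <- rep(c("Xu5P", "R5P", "Xu5P"), 2L)
  sts <- lapply(seq_len(6L), function(i)
    label_state(roles[i], pentose_states[[i]]$pattern))
  hexoses <- list(); trioses <- list()
  pool_consumed <- list(); internal_emitted <- list()
  for (set in list(sts[1:3], sts[4:6])) {
    tkt1 <- apply_reaction(net, "TKT1", set[1:2])
    s7p <- tkt1[[1]]; gap_i <- tkt1[[2]]
    if (tal_partner_policy == "internal") {
      partner <- gap_i
    } else {
      partner <- unlabeled_state(net, "GAP")
      pool_consumed <- c(pool_consumed, list(partner))
      internal_emitted <- c(internal_emitted, list(gap_i))
    }
    tal <- apply_reaction(net, "TAL", list(s7p, partner))
    e4p <- tal[[1]]; f6p_a <- tal[[2]]
    tkt2 <- apply_reaction(net, "TKT2", list(set[[3]], e4p))
    f6p_b <- tkt2[[1]]; gap_o <- tkt2[[2]]
    to_g6p <- function(f6p)
      apply_reaction(net, "PGI", list(f6p), direction = "reverse")[[1]]
    hexoses <- c(hexoses, list(to_g6p(f6p_a), to_g6p(f6p_b)))
    trioses <- c(trioses, list(gap_o))
  }
  out <- list(hexoses = hexoses, trioses = trioses)
  if (tal_partner_policy == "pool_unlabeled") {
    out$pool_consumed <- pool_consumed
    out$internal_emitted <- internal_emitted
  }
  out
}

#' Enumerate first-round tracer placements in one TKT/TAL set
#'
#' Each of the three pentose inputs of one transketolase/transaldolase set
#' (TKT1 donor Xu5P, acceptor R5P, TKT2 donor Xu5P) is independently either
#' fully labeled (m+5) or unlabeled; the all-unlabeled assignment is
#' excluded, giving the 2^3 - 1 = 7 first-round combinations. The
#' transaldolase triose partner is drawn unlabeled from the pool. For each
#' assignment the mass shifts of the two regenerated hexoses are reported.
#'
#' @param net A `ppp_network`.
#' @return Data frame with one row per assignment: logical columns
#'   `tkt1_donor`, `acceptor`, `tkt2_donor`; integer `hexose_tal` and
#'   `hexose_tkt2` (mass shifts of the TAL- and TKT2-formed hexoses); and
#'   logical `any_m2` (does the assignment regenerate an m+2 hexose?).
#' @examples
#' e <- enumerate_first_round(default_network())
#' nrow(e)        # 7 combinations
#' sum(e$any_m2)  # 3 of them regenerate an m+2 hexose
#' @export
enumerate_first_round <- function(net) {
  grid <- expand.grid(tkt1_donor = c(FALSE, TRUE),
                      acceptor = c(FALSE, TRUE),
                      tkt2_donor = c(FALSE, TRUE))
  grid <- grid[rowSums(grid) > 0L, , drop = FALSE]
  mk <- function(metab, lab)
    if (lab) full_state(net, metab) else unlabeled_state(net, metab)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    tkt1 <- apply_reaction(net, "TKT1",
                           list(mk("Xu5P", g$tkt1_donor),
                                mk("R5P", g$acceptor)))
    tal <- apply_reaction(net, "TAL",
                          list(tkt1[[1]], unlabeled_state(net, "GAP")))
    tkt2 <- apply_reaction(net, "TKT2",
                           list(mk("Xu5P", g$tkt2_donor), tal[[1]]))
    c(hexose_tal = mass_shift(tal[[2]]), hexose_tkt2 = mass_shift(tkt2[[1]]))
  })
  res <- do.call(rbind, res)
  out <- cbind(grid, as.data.frame(res))
  out$any_m2 <- out$hexose_tal == 2L | out$hexose_tkt2 == 2L
  rownames(out) <- NULL
  out
}

# ---- distribution propagation ---------------------------------------------
# A pool is a probability vector over the 2^n positional states of one
# metabolite (index = bitmask + 1). Propagation is exact: no Monte Carlo.

dist_unlabeled <- function(n) { d <- numeric(2^n); d[1] <- 1; d }

# iid per-carbon labeling probability p (tracer purity model)
dist_iid <- function(n, p) {
  d <- numeric(2^n)
  for (mask in 0:(2^n - 1)) {
    k <- bitcount(mask, n)
    d[mask + 1] <- p^k * (1 - p)^(n - k)
  }
  d
}

dist_mix <- function(d1, d2, w1) w1 * d1 + (1 - w1) * d2

# Exact marginal propagation through one reaction: substrate pools are drawn
# independently; returns the product pools (marginals).
propagate <- function(net, reaction, sub_dists,
                      direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  rxn <- resolve_reaction(net, reaction)
  side_out <- if (direction == "forward") rxn$products else rxn$substrates
  n_out <- vapply(side_out, function(m) n_carbons(net, m), 1L)
  supports <- lapply(sub_dists, function(d) which(d > 0) - 1L)
  probs <- lapply(seq_along(sub_dists),
                  function(i) sub_dists[[i]][supports[[i]] + 1L])
  out <- lapply(n_out, function(n) numeric(2^n))
  grid <- as.matrix(expand.grid(lapply(supports, seq_along)))
  for (r in seq_len(nrow(grid))) {
    idx <- grid[r, ]
    masks <- vapply(seq_along(idx), function(i) supports[[i]][idx[i]], 1L)
    p <- prod(vapply(seq_along(idx), function(i) probs[[i]][idx[i]], 1))
    pm <- apply_masks(rxn, masks, direction)
    for (j in seq_along(out))
      out[[j]][pm[j] + 1] <- out[[j]][pm[j] + 1] + p
  }
  names(out) <- NULL
  out
}

mid_from_dist <- function(d, n) {
  shifts <- vapply(0:(2^n - 1), bitcount, 1L, n = n)
  mid <- vapply(0:n, function(k) sum(d[shifts == k]), 1)
  names(mid) <- paste0("m", 0:n)
  mid
}

# ---- regimes ---------------------------------------------------------------

regime_ids <- function()
  c("direct_glycolysis", "oxppp_single_pass", "cyclic_ppp", "nonox_ppp")

#' Specify a labeling regime
#'
#' A regime describes one idealized route of tracer metabolism: direct
#' glycolysis, a single oxidative-PPP pass, cyclic PPP (with a configurable
#' number of oxidation/recombination rounds), or nonoxidative PPP run in
#' reverse from glycolytic intermediates.
#'
#' @param regime One of `"direct_glycolysis"`, `"oxppp_single_pass"`,
#'   `"cyclic_ppp"`, `"nonox_ppp"`.
#' @param tracer Entry tracer: `"glucose_m6"` (fully labeled glucose),
#'   `"trehalose_m12"` (both glucosyl units labeled) or `"trehalose_m6"`
#'   (one glucosyl unit labeled).
#' @param enrichment Fraction of the entry hexose pool that is
#'   tracer-derived, in `[0, 1]`.
#' @param rounds Number of cyclic-PPP rounds (cyclic regime only; >= 1).
#' @param purity Tracer isotopic purity, the per-carbon 13C probability of a
#'   tracer molecule (the commercial tracer is >= 99 atom % 13C).
#' @return Object of class `ppp_regime`.
#' @export
regime_spec <- function(regime, tracer = "glucose_m6", enrichment = 1,
                        rounds = 2L, purity = 1) {
  regime <- match.arg(regime, regime_ids())
  tracer <- match.arg(tracer, c("glucose_m6", "trehalose_m12",
                                "trehalose_m6"))
  stopifnot(enrichment >= 0, enrichment <= 1, purity >= 0, purity <= 1)
  rounds <- as.integer(rounds)
  if (rounds < 1L) stop("rounds must be >= 1", call. = FALSE)
  structure(list(regime = regime, tracer = tracer, enrichment = enrichment,
                 rounds = rounds, purity = purity), class = "ppp_regime")
}

# Entry glucose-6P pool: tracer mixed with unlabeled glucose at `enrichment`.
entry_hexose_dist <- function(net, spec) {
  p <- spec$purity
  tracer_glc <- switch(spec$tracer,
    glucose_m6 = dist_iid(6L, p),
    trehalose_m12 = {
      g <- propagate(net, "TREH", list(dist_iid(12L, p)))
      dist_mix(g[[1]], g[[2]], 0.5)
    },
    trehalose_m6 = {
      # one glucosyl unit labeled: carbons 1-6 at purity, 7-12 unlabeled
      d12 <- numeric(2^12)
      d6 <- dist_iid(6L, p)
      d12[seq_len(64L)] <- d6  # masks 0..63 leave carbons 7-12 unlabeled
      g <- propagate(net, "TREH", list(d12))
      dist_mix(g[[1]], g[[2]], 0.5)
    })
  dist_mix(tracer_glc, dist_unlabeled(6L), spec$enrichment)
}

cleave_hexose <- function(net, hex_dist) {
  g <- propagate(net, "ALD", list(hex_dist))
  dist_mix(g[[1]], g[[2]], 0.5)
}

oxidize_hexose <- function(net, hex_dist)
  propagate(net, "OXPPP", list(hex_dist))[[2]]

# Nonoxidative PPP run in reverse: 2 F6P + GAP -> 2 Xu5P + R5P (+ S7P
# intermediate). Enumerated jointly over the two hexose draws and the triose
# draw so within-lineage carbon correlations are exact.
nonox_pools <- function(net, hex_dist, gap_dist) {
  nb <- function(d) which(d > 0) - 1L
  s_f <- nb(hex_dist); s_g <- nb(gap_dist)
  xu1 <- numeric(2^5); xu2 <- numeric(2^5); r5p <- numeric(2^5)
  s7p <- numeric(2^7)
  tkt2 <- net$reactions[["TKT2"]]; tal <- net$reactions[["TAL"]]
  tkt1 <- net$reactions[["TKT1"]]
  for (f1 in s_f) for (f2 in s_f) for (g in s_g) {
    p <- hex_dist[f1 + 1] * hex_dist[f2 + 1] * gap_dist[g + 1]
    r1 <- apply_masks(tkt2, c(f1, g), "reverse")        # Xu5P, E4P
    r2 <- apply_masks(tal, c(r1[2], f2), "reverse")     # S7P, GAP'
    r3 <- apply_masks(tkt1, r2, "reverse")              # Xu5P, R5P
    xu1[r1[1] + 1] <- xu1[r1[1] + 1] + p
    s7p[r2[1] + 1] <- s7p[r2[1] + 1] + p
    xu2[r3[1] + 1] <- xu2[r3[1] + 1] + p
    r5p[r3[2] + 1] <- r5p[r3[2] + 1] + p
  }
  list(xu1 = xu1, xu2 = xu2, r5p = r5p, s7p = s7p)
}

#' Simulate the mass isotopologue distributions of one labeling regime
#'
#' Propagates the tracer exactly (full positional-state enumeration, no
#' sampling) through the route defined by the regime and returns the mass
#' isotopologue distribution (MID) of each reported species. Species the
#' instrument cannot resolve are reported combined: `Ru5P_R5P` is the
#' RPI/RPE-equilibrated pentose-phosphate pool and `F6P_G1P` the combined
#' hexose-phosphate signal.
#'
#' For the cyclic regime the hexose pool re-enters oxidation each round,
#' diluted by unlabeled endogenous influx at the stated enrichment, and the
#' transaldolase triose partner is drawn from the glycolytic triose pool;
#' reported pools are those of the final round.
#'
#' @param net A `ppp_network`.
#' @param spec A [regime_spec()].
#' @return Named list of MIDs (numeric vectors `m0..mn` summing to 1) for
#'   G6P, F6P_G1P, Ru5P_R5P, S7P, GAP and lactate.
#' @export
simulate_regime <- function(net, spec) {
  if (!inherits(spec, "ppp_regime"))
    stop("spec must be a ppp_regime", call. = FALSE)
  hin <- entry_hexose_dist(net, spec)
  gap_gly <- cleave_hexose(net, hin)
  un5 <- dist_unlabeled(5L); un7 <- dist_unlabeled(7L)
  pools <- switch(spec$regime,
    direct_glycolysis = list(G6P = hin, F6P = hin, pentose = un5,
                             S7P = un7, GAP = gap_gly),
    oxppp_single_pass = {
      ru <- oxidize_hexose(net, hin)
      tkt1 <- propagate(net, "TKT1", list(ru, ru))
      list(G6P = hin, F6P = hin, pentose = ru, S7P = tkt1[[1]],
           GAP = tkt1[[2]])
    },
    cyclic_ppp = {
      h <- hin
      for (k in seq_len(spec$rounds)) {
        pent <- oxidize_hexose(net, h)
        tkt1 <- propagate(net, "TKT1", list(pent, pent))
        s7p <- tkt1[[1]]; gap_i <- tkt1[[2]]
        tal <- propagate(net, "TAL", list(s7p, gap_gly))
        e4p <- tal[[1]]; f6p_a <- tal[[2]]
        tkt2 <- propagate(net, "TKT2", list(pent, e4p))
        f6p_b <- tkt2[[1]]; gap_o <- tkt2[[2]]
        recycled <- dist_mix(f6p_a, f6p_b, 0.5)
        h <- dist_mix(recycled, dist_unlabeled(6L), spec$enrichment)
      }
      list(G6P = recycled, F6P = recycled, pentose = pent, S7P = s7p,
           GAP = dist_mix(gap_i, gap_o, 0.5))
    },
    nonox_ppp = {
      np <- nonox_pools(net, hin, gap_gly)
      pent <- (np$xu1 + np$xu2 + np$r5p) / 3
      list(G6P = hin, F6P = hin, pentose = pent, S7P = np$s7p,
           GAP = gap_gly)
    })
  list(G6P = mid_from_dist(pools$G6P, 6L),
       F6P_G1P = mid_from_dist(pools$F6P, 6L),
       Ru5P_R5P = mid_from_dist(pools$pentose, 5L),
       S7P = mid_from_dist(pools$S7P, 7L),
       GAP = mid_from_dist(pools$GAP, 3L),
       lactate = mid_from_dist(pools$GAP, 3L))
}

#' Regime template MIDs for mixture deconvolution
#'
#' Simulates every requested regime under a common tracer setting and stacks
#' the per-metabolite MIDs into the template matrix used by
#' [fit_pathway_mixture()].
#'
#' @param net A `ppp_network`.
#' @param regimes Character vector of regime ids (default all four).
#' @param tracer,enrichment,rounds,purity Passed to [regime_spec()].
#' @param metabolites Reported species to include in the stacked matrix.
#' @return Object of class `ppp_templates`: list with `mids` (list
#'   regime -> metabolite -> MID), `matrix` (stacked fractions, one column
#'   per regime, rows named `<metabolite>.m<k>`), and the settings used.
#' @export
template_mids <- function(net, regimes = regime_ids(),
                          tracer = "glucose_m6", enrichment = 1,
                          rounds = 2L, purity = 1,
                          metabolites = c("G6P", "F6P_G1P", "Ru5P_R5P",
                                          "S7P", "lactate")) {
  regimes <- match.arg(regimes, regime_ids(), several.ok = TRUE)
  mids <- lapply(regimes, function(r)
    simulate_regime(net, regime_spec(r, tracer = tracer,
                                     enrichment = enrichment,
                                     rounds = rounds, purity = purity)))
  names(mids) <- regimes
  mat <- vapply(mids, function(m) unlist(m[metabolites]),
                numeric(length(unlist(mids[[1]][metabolites]))))
  rownames(mat) <- unlist(lapply(metabolites, function(mb)
    paste0(mb, ".", names(mids[[1]][[mb]]))))
  structure(list(mids = mids, matrix = mat, metabolites = metabolites,
                 tracer = tracer, enrichment = enrichment, rounds = rounds,
                 purity = purity),
            class = "ppp_templates")
}

#' @export
print.ppp_templates <- function(x, ...) {
  cat("Regime MID templates:", paste(colnames(x$matrix), collapse = ", "),
      "\n  tracer:", x$tracer, " enrichment:", x$enrichment,
      " rounds:", x$rounds, " purity:", x$purity, "\n  metabolites:",
      paste(x$metabolites, collapse = ", "), "\n")
  invisible(x)
}

#' Write / read MIDs as a long CSV
#'
#' Columns: `metabolite`, `mass_shift`, `fraction`, `regime`.
#'
#' @param mids Named list (regime -> metabolite -> MID vector), or the
#'   `mids` element of a `ppp_templates`.
#' @param path CSV path.
#' @return `path` invisibly; `read_mids` returns the nested list.
#' @export
write_mids <- function(mids, path) {
  rows <- do.call(rbind, lapply(names(mids), function(rg) {
    do.call(rbind, lapply(names(mids[[rg]]), function(mb) {
      v <- mids[[rg]][[mb]]
      data.frame(metabolite = mb, mass_shift = seq_along(v) - 1L,
                 fraction = as.numeric(v), regime = rg)
    }))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mids
#' @export
read_mids <- function(path) {
  df <- utils::read.csv(path)
  out <- lapply(split(df, df$regime), function(dr) {
    lapply(split(dr, dr$metabolite), function(dm) {
      dm <- dm[order(dm$mass_shift), ]
      v <- dm$fraction
      names(v) <- paste0("m", dm$mass_shift)
      v
    })
  })
  out
}
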