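#' Declare a metabolite
#'
#' A metabolite is identified by name and carries a fixed carbon count.
#' Aliases record isobaric species the instrument cannot resolve from it
#' (e.g. glucose-1P reported together with fructose-6P).
#'
#' @param name Metabolite identifier (single string).
#' @param n_carbons Number of carbon atoms (positive integer).
#' @param aliases Character vector of unresolvable co-reported species.
#' @return An object of class `ppp_metabolite`.
#' @export
ppp_metabolite <- function(name, n_carbons, aliases = character()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  n_carbons <- as.integer(n_carbons)
  if (is.na(n_carbons) || n_carbons < 1L)
    stop("n_carbons must be a positive integer", call. = FALSE)
  structure(list(name = name, n_carbons = n_carbons,
                 aliases = as.character(aliases)),
            class = "ppp_metabolite")
}

#' Declare an atom-mapped reaction
#'
#' The carbon map sends each substrate carbon to exactly one product carbon
#' (a bijection; CO2 counts as a one-carbon product). Carbons are numbered
#' by biochemical convention, C1 at the most oxidized end.
#'
#' @param name Reaction identifier.
#' @param substrates,products Character vectors of metabolite names, in
#'   positional order (a metabolite may appear twice, e.g. two GAP products).
#' @param carbon_map Data frame with integer columns `sub`, `sub_c`, `prod`,
#'   `prod_c`: substrate index, substrate carbon, product index, product
#'   carbon.
#' @param reversible Logical; may the reaction be applied in reverse?
#' @return An object of class `ppp_reaction`.
#' @export
ppp_reaction <- function(name, substrates, products, carbon_map,
                         reversible = FALSE) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(substrates), is.character(products),
            is.data.frame(carbon_map),
            all(c("sub", "sub_c", "prod", "prod_c") %in% names(carbon_map)))
  cm <- carbon_map[, c("sub", "sub_c", "prod", "prod_c")]
  cm[] <- lapply(cm, as.integer)
  structure(list(name = name, substrates = substrates, products = products,
                 carbon_map = cm, reversible = isTRUE(reversible)),
            class = "ppp_reaction")
}

#' Assemble a carbon-transition network
#'
#' @param metabolites List of [ppp_metabolite()] objects.
#' @param reactions List of [ppp_reaction()] objects.
#' @param reporting Named list mapping a reported (combined) species name to
#'   the network metabolites pooled under it by the instrument.
#' @return An object of class `ppp_network`.
#' @export
ppp_network <- function(metabolites, reactions, reporting = list()) {
  names(metabolites) <- vapply(metabolites, `[[`, "", "name")
  if (anyDuplicated(names(metabolites)))
    stop("metabolite names must be unique", call. = FALSE)
  names(reactions) <- vapply(reactions, `[[`, "", "name")
  net <- structure(list(metabolites = metabolites, reactions = reactions,
                        reporting = reporting),
                   class = "ppp_network")
  bad <- validate_network(net)
  bad <- bad[grepl("undeclared metabolite", bad)]
  if (length(bad)) stop(paste(bad, collapse = "; "), call. = FALSE)
  net
}

#' Number of carbons of a metabolite in a network
#' @param net A `ppp_network`.
#' @param metabolite Metabolite name.
#' @return Integer carbon count.
#' @export
n_carbons <- function(net, metabolite) {
  m <- net$metabolites[[metabolite]]
  if (is.null(m)) stop("unknown metabolite: ", metabolite, call. = FALSE)
  m$n_carbons
}

#' The shipped trehalose/glycolysis/PPP network
#'
#' Trehalose cleavage to two glucose units, upper glycolysis, the oxidative
#' PPP lump (6-phosphogluconate decarboxylation: G6P loses C1 as CO2, C2-C6
#' become ribulose-5P C1-C5), pentose interconversions, the transketolase/
#' transaldolase reactions of the nonoxidative branch, the aldolase/TPI lump
#' splitting hexose into two trioses, and lower glycolysis to lactate.
#' Transketolase transfers the C1-C2 unit of its ketose donor; transaldolase
#' transfers the C1-C3 dihydroxyacetone unit.
#'
#' Ribulose-5P/ribose-5P and fructose-6P/glucose-1P are isobaric pairs the
#' LC-HRMS assay reports as single combined species; the network records
#' these under `reporting`.
#'
#' @return A `ppp_network`.
#' @examples
#' net <- default_network()
#' validate_network(net)
#' @export
default_network <- function() {
  mets <- list(
    ppp_metabolite("trehalose", 12),
    ppp_metabolite("glucose", 6),
    ppp_metabolite("G6P", 6),
    ppp_metabolite("F6P", 6, aliases = "G1P"),
    ppp_metabolite("Ru5P", 5),
    ppp_metabolite("R5P", 5),
    ppp_metabolite("Xu5P", 5),
    ppp_metabolite("S7P", 7),
    ppp_metabolite("E4P", 4),
    ppp_metabolite("GAP", 3),
    ppp_metabolite("pyruvate", 3),
    ppp_metabolite("lactate", 3),
    ppp_metabolite("CO2", 1)
  )
  cmap <- function(sub, sub_c, prod, prod_c)
    data.frame(sub = sub, sub_c = sub_c, prod = prod, prod_c = prod_c)
  ident <- function(n) cmap(1L, seq_len(n), 1L, seq_len(n))
  rxns <- list(
    # trehalose is two glucosyl units; each maps unit-wise onto one glucose
    ppp_reaction("TREH", "trehalose", c("glucose", "glucose"),
                 rbind(cmap(1L, 1:6, 1L, 1:6), cmap(1L, 7:12, 2L, 1:6))),
    ppp_reaction("HK", "glucose", "G6P", ident(6)),
    ppp_reaction("PGI", "G6P", "F6P", ident(6), reversible = TRUE),
    # oxidative-PPP lump: C1 leaves as CO2, C2..C6 -> Ru5P C1..C5
    ppp_reaction("OXPPP", "G6P", c("CO2", "Ru5P"),
                 rbind(cmap(1L, 1L, 1L, 1L), cmap(1L, 2:6, 2L, 1:5))),
    ppp_reaction("RPI", "Ru5P", "R5P", ident(5), reversible = TRUE),
    ppp_reaction("RPE", "Ru5P", "Xu5P", ident(5), reversible = TRUE),
    # transketolase 1: Xu5P C1-C2 unit onto R5P; Xu5P C3-C5 leave as GAP
    ppp_reaction("TKT1", c("Xu5P", "R5P"), c("S7P", "GAP"),
                 rbind(cmap(1L, 1:2, 1L, 1:2), cmap(2L, 1:5, 1L, 3:7),
                       cmap(1L, 3:5, 2L, 1:3)),
                 reversible = TRUE),
    # transaldolase: S7P C1-C3 unit onto GAP (-> F6P C1-C3); S7P C4-C7 -> E4P
    ppp_reaction("TAL", c("S7P", "GAP"), c("E4P", "F6P"),
                 rbind(cmap(1L, 1:3, 2L, 1:3), cmap(1L, 4:7, 1L, 1:4),
                       cmap(2L, 1:3, 2L, 4:6)),
                 reversible = TRUE),
    # transketolase 2: Xu5P C1-C2 unit onto E4P (-> F6P C1-C2)
    ppp_reaction("TKT2", c("Xu5P", "E4P"), c("F6P", "GAP"),
                 rbind(cmap(1L, 1:2, 1L, 1:2), cmap(2L, 1:4, 1L, 3:6),
                       cmap(1L, 3:5, 2L, 1:3)),
                 reversible = TRUE),
    # aldolase/TPI lump: C4-C6 -> GAP1 C1-C3; C1-C3 -> GAP2 with order
    # inverted by triose-phosphate isomerase
    ppp_reaction("ALD", "F6P", c("GAP", "GAP"),
                 rbind(cmap(1L, 4:6, 1L, 1:3), cmap(1L, 1:3, 2L, 3:1))),
    ppp_reaction("PYK", "GAP", "pyruvate", ident(3)),
    ppp_reaction("LDH", "pyruvate", "lactate", ident(3))
  )
  ppp_network(mets, rxns,
              reporting = list(Ru5P_R5P = c("Ru5P", "R5P"),
                               F6P_G1P = "F6P"))
}

#' Validate a carbon-transition network
#'
#' Checks, for every reaction: all referenced metabolites are declared;
#' substrate and product carbon totals balance; and the carbon map is a
#' bijection (every substrate carbon mapped exactly once, every product
#' carbon produced exactly once, all indices within range).
#'
#' @param net A `ppp_network`.
#' @return Character vector of human-readable violations; empty if valid.
#' @export
validate_network <- function(net) {
  bad <- character()
  ncar <- function(m) net$metabolites[[m]]$n_carbons
  for (rx in net$reactions) {
    miss <- setdiff(c(rx$substrates, rx$products), names(net$metabolites))
    if (length(miss)) {
      bad <- c(bad, paste0(rx$name, ": undeclared metabolite ",
                           paste(miss, collapse = ", ")))
      next
    }
    ns <- vapply(rx$substrates, ncar, 1L)
    np <- vapply(rx$products, ncar, 1L)
    if (sum(ns) != sum(np))
      bad <- c(bad, paste0(rx$name, ": carbon imbalance (", sum(ns),
                           " in, ", sum(np), " out)"))
    cm <- rx$carbon_map
    ok_idx <- cm$sub >= 1L & cm$sub <= length(ns) &
      cm$prod >= 1L & cm$prod <= length(np)
    ok_idx[ok_idx] <- cm$sub_c[ok_idx] >= 1L &
      cm$sub_c[ok_idx] <= ns[cm$sub[ok_idx]] &
      cm$prod_c[ok_idx] >= 1L & cm$prod_c[ok_idx] <= np[cm$prod[ok_idx]]
    if (!all(ok_idx)) {
      bad <- c(bad, paste0(rx$name, ": carbon index out of range"))
      next
    }
    skey <- paste(cm$sub, cm$sub_c)
    pkey <- paste(cm$prod, cm$prod_c)
    sall <- unlist(lapply(seq_along(ns),
                          function(i) paste(i, seq_len(ns[i]))))
    pall <- unlist(lapply(seq_along(np),
                          function(i) paste(i, seq_len(np[i]))))
    if (anyDuplicated(skey))
      bad <- c(bad, paste0(rx$name, ": substrate carbon mapped twice"))
    if (anyDuplicated(pkey))
      bad <- c(bad, paste0(rx$name,
                           ": non-injective map (product carbon hit twice)"))
    un_s <- setdiff(sall, skey)
    if (length(un_s))
      bad <- c(bad, paste0(rx$name, ": unmapped substrate carbon (",
                           length(un_s), ")"))
    un_p <- setdiff(pall, pkey)
    if (length(un_p))
      bad <- c(bad, paste0(rx$name, ": unmapped product carbon (",
                           length(un_p), ")"))
  }
  bad
}

#' @export
print.ppp_network <- function(x, ...) {
  cat("Carbon-transition network:", length(x$metabolites), "metabolites,",
      length(x$reactions), "reactions\n")
  for (rx in x$reactions)
    cat(sprintf("  %-6s %s %s %s\n", rx$name,
                paste(rx$substrates, collapse = " + "),
                if (rx$reversible) "<->" else "-->",
                paste(rx$products, collapse = " + ")))
  invisible(x)
}

#' @export
print.ppp_reaction <- function(x, ...) {
  cat(sprintf("%s: %s %s %s (%d mapped carbons)\n", x$name,
              paste(x$substrates, collapse = " + "),
              if (x$reversible) "<->" else "-->",
              paste(x$products, collapse = " + "), nrow(x$carbon_map)))
  invisible(x)
}

#' Write a network to a plain-text declarative file
#'
#' One record per line. Metabolite lines: `metabolite <name> <n_carbons>
#' [alias,...]`. Reaction lines: `reaction <name> <rev|irr> | A + B -> C + D
#' | s.c>p.c ...` where `s.c>p.c` maps substrate `s` carbon `c` onto a
#' product carbon. [read_network()] round-trips the format.
#'
#' @param net A `ppp_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  lines <- "# ppptracer network v1"
  for (m in net$metabolites) {
    ln <- paste("metabolite", m$name, m$n_carbons)
    if (length(m$aliases)) ln <- paste(ln, paste(m$aliases, collapse = ","))
    lines <- c(lines, ln)
  }
  for (g in names(net$reporting))
    lines <- c(lines, paste("reporting", g,
                            paste(net$reporting[[g]], collapse = ",")))
  for (rx in net$reactions) {
    cm <- rx$carbon_map
    lines <- c(lines, paste(
      "reaction", rx$name, if (rx$reversible) "rev" else "irr", "|",
      paste(rx$substrates, collapse = " + "), "->",
      paste(rx$products, collapse = " + "), "|",
      paste(sprintf("%d.%d>%d.%d", cm$sub, cm$sub_c, cm$prod, cm$prod_c),
            collapse = " ")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a network from the plain-text declarative format
#'
#' @param path File written by [write_network()].
#' @return A `ppp_network`.
#' @export
read_network <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  mets <- list(); rxns <- list(); reporting <- list()
  for (ln in lines) {
    tok <- strsplit(ln, "\\s+")[[1]]
    if (tok[1] == "metabolite") {
      aliases <- if (length(tok) >= 4) strsplit(tok[4], ",")[[1]] else character()
      mets[[length(mets) + 1L]] <-
        ppp_metabolite(tok[2], as.integer(tok[3]), aliases)
    } else if (tok[1] == "reporting") {
      reporting[[tok[2]]] <- strsplit(tok[3], ",")[[1]]
    } else if (tok[1] == "reaction") {
      parts <- strsplit(ln, "\\|")[[1]]
      head_tok <- strsplit(trimws(parts[1]), "\\s+")[[1]]
      eq <- strsplit(trimws(parts[2]), "->", fixed = TRUE)[[1]]
      subs <- trimws(strsplit(eq[1], "+", fixed = TRUE)[[1]])
      prods <- trimws(strsplit(eq[2], "+", fixed = TRUE)[[1]])
      pairs <- strsplit(trimws(parts[3]), "\\s+")[[1]]
      mm <- do.call(rbind, lapply(pairs, function(p) {
        as.integer(strsplit(p, "[.>]")[[1]])
      }))
      cm <- data.frame(sub = mm[, 1], sub_c = mm[, 2],
                       prod = mm[, 3], prod_c = mm[, 4])
      rxns[[length(rxns) + 1L]] <-
        ppp_reaction(head_tok[2], subs, prods, cm,
                     reversible = head_tok[3] == "rev")
    } else stop("unrecognized network record: ", ln, call. = FALSE)
  }
  ppp_network(mets, rxns, reporting)
}
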