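#' Validate / construct a long-format peak-area table
#'
#' The pipeline's tabular currency: one row per (sample, metabolite, mass
#' shift) with a nonnegative chromatographic peak area. Extra columns are
#' preserved.
#'
#' @param df Data frame with columns `sample_id`, `group`, `metabolite`,
#'   `mass_shift`, `peak_area` and optionally `stage`
#'   (raw/corrected/normalized).
#' @return The validated data frame (class `ppp_areas` prepended).
#' @export
peak_area_table <- function(df) {
  need <- c("sample_id", "group", "metabolite", "mass_shift", "peak_area")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("peak-area table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!("stage" %in% names(df))) df$stage <- "raw"
  df$mass_shift <- as.integer(df$mass_shift)
  if (anyNA(df$mass_shift) || any(df$mass_shift < 0))
    stop("mass_shift must be a nonnegative integer", call. = FALSE)
  if (any(!is.finite(df$peak_area)) || any(df$peak_area < 0))
    stop("peak_area must be finite and nonnegative", call. = FALSE)
  key <- paste(df$sample_id, df$metabolite, df$mass_shift)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate (sample, metabolite, mass_shift) record: ", d,
         call. = FALSE)
  }
  class(df) <- unique(c("ppp_areas", class(df)))
  df
}

#' Read / write peak-area tables as CSV
#'
#' @param path CSV file with header `sample_id,group,metabolite,mass_shift,
#'   peak_area[,stage]`.
#' @return `read_peak_areas`: a validated table; `write_peak_areas`: `path`
#'   invisibly.
#' @export
read_peak_areas <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tryCatch(peak_area_table(df), error = function(e)
    stop("malformed peak-area table '", path, "': ", conditionMessage(e),
         call. = FALSE))
}

#' @rdname read_peak_areas
#' @param table A peak-area table.
#' @export
write_peak_areas <- function(table, path) {
  utils::write.csv(as.data.frame(unclass(table))[
    , c("sample_id", "group", "metabolite", "mass_shift", "peak_area",
        "stage")], path, row.names = FALSE)
  invisible(path)
}

m0_areas <- function(table, sample_id, exclude) {
  s <- table[table$sample_id == sample_id & table$mass_shift == 0L &
               !(table$metabolite %in% exclude), ]
  stats::setNames(s$peak_area, s$metabolite)
}

#' Per-sample normalization factor against a reference sample
#'
#' For every screened metabolite, the unlabeled (m+0) peak area of the
#' sample is divided by the m+0 area of the same metabolite in the
#' reference sample; the arithmetic mean of these ratios over all usable
#' metabolites is the sample's normalization factor. Metabolites absent
#' from either sample or with zero reference area are excluded (and
#' counted). Labeled satellites never enter the factor.
#'
#' @param table A peak-area table containing both samples.
#' @param sample_id Sample whose factor is computed.
#' @param reference_id Reference sample.
#' @param exclude Metabolites excluded from the factor (internal standards;
#'   default the 4-fluorophenylalanine spike-in).
#' @return List of class `ppp_normfactor`: `sample_id`, `factor`,
#'   `n_metabolites_used`, `n_excluded`.
#' @export
normalization_factor <- function(table, sample_id, reference_id,
                                 exclude = "4-fluorophenylalanine") {
  a_s <- m0_areas(table, sample_id, exclude)
  a_r <- m0_areas(table, reference_id, exclude)
  shared <- intersect(names(a_s), names(a_r))
  usable <- shared[a_r[shared] > 0]
  if (!length(usable))
    stop("no shared metabolite with positive reference m+0 area between ",
         sample_id, " and ", reference_id, call. = FALSE)
  ratios <- a_s[usable] / a_r[usable]
  structure(list(sample_id = sample_id, factor = mean(ratios),
                 n_metabolites_used = length(usable),
                 n_excluded = length(shared) - length(usable)),
            class = "ppp_normfactor")
}

#' @export
print.ppp_normfactor <- function(x, ...) {
  cat(sprintf("normalization factor %s: %.6g (%d metabolites, %d excluded)\n",
              x$sample_id, x$factor, x$n_metabolites_used, x$n_excluded))
  invisible(x)
}

#' Normalize a peak-area table to a reference sample
#'
#' Computes one [normalization_factor()] per sample and divides every peak
#' area of that sample by its factor; the reference sample's factor is 1 by
#' construction. Normalization is idempotent and invariant to per-sample
#' global rescaling.
#'
#' @param table A peak-area table.
#' @param reference_id Reference sample id.
#' @param exclude Metabolites excluded from the factors.
#' @return The normalized table, with stage `"normalized"` and an attribute
#'   `factors` (data frame of per-sample factors).
#' @export
normalize_table <- function(table, reference_id,
                            exclude = "4-fluorophenylalanine") {
  table <- peak_area_table(as.data.frame(table))
  samples <- unique(table$sample_id)
  if (!(reference_id %in% samples))
    stop("reference sample '", reference_id, "' not present", call. = FALSE)
  facs <- lapply(samples, function(s)
    normalization_factor(table, s, reference_id, exclude))
  fv <- stats::setNames(vapply(facs, `[[`, 1, "factor"), samples)
  table$peak_area <- table$peak_area / fv[table$sample_id]
  table$stage <- "normalized"
  attr(table, "factors") <- data.frame(
    sample_id = samples, factor = unname(fv),
    n_metabolites_used = vapply(facs, `[[`, 1L, "n_metabolites_used"))
  table
}

#' Isotopologue fractions of one (sample, metabolite) block
#'
#' Each mass-shift area is divided by the summed area of the block:
#' `fraction(m+k) = area(m+k) / sum(areas)`. Missing mass-shift rows count
#' as zero area.
#'
#' @param slice Peak-area table rows for one sample and one metabolite (or
#'   a full table plus `sample_id`/`metabolite` to select them).
#' @param n_carbons Carbon count of the species; defaults to the largest
#'   mass shift present.
#' @param sample_id,metabolite Optional selectors applied to `slice`.
#' @return Numeric MID vector `m0..mn` summing to 1.
#' @export
compute_fractions <- function(slice, n_carbons = NULL, sample_id = NULL,
                              metabolite = NULL) {
  if (!is.null(sample_id)) slice <- slice[slice$sample_id == sample_id, ]
  if (!is.null(metabolite)) slice <- slice[slice$metabolite == metabolite, ]
  if (!nrow(slice)) stop("empty (sample, metabolite) slice", call. = FALSE)
  if (length(unique(slice$sample_id)) > 1L ||
      length(unique(slice$metabolite)) > 1L)
    stop("slice must cover exactly one sample and one metabolite",
         call. = FALSE)
  if (is.null(n_carbons)) n_carbons <- max(slice$mass_shift)
  if (any(slice$mass_shift > n_carbons))
    stop("mass shift exceeds carbon count for ", slice$metabolite[1],
         call. = FALSE)
  areas <- numeric(n_carbons + 1L)
  areas[slice$mass_shift + 1L] <- slice$peak_area
  tot <- sum(areas)
  if (tot <= 0)
    stop("all-zero areas for ", slice$sample_id[1], "/",
         slice$metabolite[1], call. = FALSE)
  stats::setNames(areas / tot, paste0("m", 0:n_carbons))
}

#' Isotopologue fractions for every (sample, metabolite) block of a table
#'
#' @param table A peak-area table.
#' @param n_carbons Optional named integer vector (metabolite -> carbon
#'   count); defaults per metabolite to the largest shift present.
#' @return Long data frame: `sample_id`, `group`, `metabolite`,
#'   `mass_shift`, `fraction`.
#' @export
fraction_table <- function(table, n_carbons = NULL) {
  blocks <- split(as.data.frame(table),
                  list(table$sample_id, table$metabolite), drop = TRUE)
  out <- lapply(blocks, function(b) {
    nc <- if (!is.null(n_carbons)) unname(n_carbons[b$metabolite[1]]) else NULL
    fr <- compute_fractions(b, n_carbons = nc)
    data.frame(sample_id = b$sample_id[1], group = b$group[1],
               metabolite = b$metabolite[1],
               mass_shift = seq_along(fr) - 1L, fraction = as.numeric(fr))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$metabolite, out$sample_id, out$mass_shift), ]
}
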