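# Per-taxon bias statistics: occurrence tallies, robust per-species
# summaries, sampling-coverage proportions, origin/completeness shares, and
# the deviation from an ideal species-proportional sampling.

# Unscaled MAD: the literal median of absolute deviations from the median
# (no 1.4826 normal-consistency factor).
mad_raw <- function(x) stats::median(abs(x - stats::median(x)))

#' Ideal species-proportional occurrence count
#'
#' Under unbiased taxonomic sampling each taxon would receive occurrences in
#' proportion to its known species richness: `I = NB_occ * (N / N_tot)`.
#'
#' @param NB_occ total occurrences over all taxa.
#' @param N known species of the focal taxon.
#' @param N_tot known species over all taxa.
#' @return the ideal occurrence count I (numeric).
#' @export
ideal_sampling <- function(NB_occ, N, N_tot) {
  if (any(N_tot <= 0)) stop("N_tot must be > 0")
  if (any(N < 0 | N > N_tot)) stop("need 0 <= N <= N_tot")
  NB_occ * (N / N_tot)
}

#' Deviation from the ideal sampling
#' @param nb_occ observed occurrence count of a taxon.
#' @param I ideal count from [ideal_sampling()].
#' @return signed deviation `nb_occ - I`; positive = over-represented.
#' @export
deviation <- function(nb_occ, I) nb_occ - I

#' Per-taxon occurrence summary statistics
#'
#' For each class (or order) computes: total occurrences `nb_occ`; the
#' number `n_gt1` of distinct recorded species; the known species richness
#' `N` from the backbone; median and raw MAD of occurrences per recorded
#' species (`med_sp`, `mad`); the taxonomic precision (proportion of
#' occurrences identified to species level or lower); the coverage
#' proportions `p_gt1 = n_gt1/N`, `p_gt20 = n_gt20/N` and `p_gt20d`
#' (species with >= 20 spatially distinct occurrences on the equal-area
#' grid); origin shares `o_spec`, `o_obs`, `o_unk`; and the incompleteness
#' proportions `p_time`, `p_space`.
#'
#' @param records normalized occurrence table ([normalize_occurrences()]).
#' @param backbone backbone table; known richness is counted per taxon at
#'   the requested level.
#' @param level `"class"` or `"order"`; order-level summaries drop (and
#'   tally) records without an order affiliation.
#' @param cell_size grid cell edge in metres for the spatially-distinct
#'   criterion.
#' @param distinct_threshold occurrence threshold for "decent" sampling
#'   (default 20).
#' @return a `data.table`, one row per taxon, with an `excluded` attribute
#'   tallying records without taxon affiliation.
#' @export
summarize_taxa <- function(records, backbone, level = c("class", "order"),
                           cell_size = 10000, distinct_threshold = 20L) {
  level <- match.arg(level)
  dt <- as.data.table(records)
  key <- if (level == "class") "class_name" else "order_name"
  excluded <- sum(!nzchar(dt[[key]]))
  dt <- dt[nzchar(get(key))]
  bb <- as.data.table(backbone)[status %in% c("accepted", "doubtful")]
  bkey <- if (level == "class") "class_name" else "order_name"
  known <- bb[, .(N = length(unique(species))), by = bkey]
  setnames(known, bkey, "taxon")

  per_sp <- dt[nzchar(species), .(n_occ = .N), by = c(key, "species")]
  setnames(per_sp, key, "taxon")

  dcells <- dt[nzchar(get(key)),
               distinct_cells_by_species(.SD, cell_size = cell_size),
               by = key]
  setnames(dcells, key, "taxon")
  per_sp <- merge(per_sp, dcells, by = c("taxon", "species"), all.x = TRUE)
  per_sp[is.na(n_cells), n_cells := 0L]

  sp_stats <- per_sp[, .(
    n_gt1 = .N,
    med_sp = as.numeric(stats::median(n_occ)),
    mad = as.numeric(mad_raw(n_occ)),
    n_gt20 = sum(n_occ >= distinct_threshold),
    n_gt20d = sum(n_cells >= distinct_threshold)
  ), by = taxon]

  occ_stats <- dt[, .(
    nb_occ = .N,
    precision = mean(species_precise),
    o_spec = mean(origin == "Specimen"),
    o_obs = mean(origin == "Observation"),
    o_unk = mean(origin == "Unknown"),
    p_time = mean(time_issue),
    p_space = mean(space_issue)
  ), by = key]
  setnames(occ_stats, key, "taxon")

  out <- merge(occ_stats, sp_stats, by = "taxon", all.x = TRUE)
  out <- merge(out, known, by = "taxon", all.x = TRUE)
  out[is.na(n_gt1), c("n_gt1", "n_gt20", "n_gt20d") := .(0L, 0L, 0L)]
  out[, p_gt1 := ifelse(!is.na(N) & N > 0, n_gt1 / N, NA_real_)]
  out[, p_gt20 := ifelse(!is.na(N) & N > 0, n_gt20 / N, NA_real_)]
  out[, p_gt20d := ifelse(!is.na(N) & N > 0, n_gt20d / N, NA_real_)]
  setorder(out, -nb_occ)
  setattr(out, "excluded", excluded)
  out[]
}

#' Taxonomic-bias deviations over time
#'
#' Recomputes the ideal sampling I and the signed deviation D for each class
#' at decadal checkpoints, using the cumulative occurrence count up to each
#' checkpoint year.  Undated records are excluded, as are records from the
#' last 10 years before the export year (data-integration lag).  Known
#' species counts N are held at their present-day backbone values.
#'
#' @param records normalized occurrence table.
#' @param backbone backbone table.
#' @param checkpoints checkpoint years (default 1956, 1966, ..., 2006).
#' @param export_year the snapshot year; records with
#'   `year > export_year - 10` are excluded.
#' @return `data.table` with columns `taxon`, `checkpoint`, `nb_occ`, `I`,
#'   `D`, `sign` (`over`/`under`/`balanced`).
#' @export
temporal_deviations <- function(records, backbone,
                                checkpoints = seq(1956, 2006, by = 10),
                                export_year = 2016) {
  dt <- as.data.table(records)
  dt <- dt[nzchar(class_name) & !is.na(year) & year <= export_year - 10]
  Ns <- count_known_species(as.data.table(backbone))
  classes <- names(Ns)
  N_tot <- sum(Ns)
  out <- rbindlist(lapply(checkpoints, function(cp) {
    sub <- dt[year <= cp]
    nb <- sub[, .N, by = class_name]
    nb_vec <- setNames(rep(0L, length(classes)), classes)
    nb_vec[nb$class_name[nb$class_name %in% classes]] <-
      nb$N[nb$class_name %in% classes]
    NB_occ <- sum(nb_vec)
    I <- if (NB_occ > 0) ideal_sampling(NB_occ, Ns, N_tot) else rep(0, length(classes))
    D <- as.numeric(nb_vec) - I
    data.table(
      taxon = classes, checkpoint = cp, nb_occ = as.integer(nb_vec),
      I = I, D = D,
      D_norm = if (NB_occ > 0) D / NB_occ else 0,
      sign = ifelse(D > 0, "over", ifelse(D < 0, "under", "balanced"))
    )
  }))
  out[]
}

#' Histogram of species by occurrence-count class
#'
#' Shares of recorded species with exactly one occurrence, 2-19
#' occurrences, and 20 or more.
#'
#' @param counts integer vector of per-species occurrence counts (>= 1).
#' @return named numeric vector `c(one=, few=, many=)` summing to 1.
#' @export
occurrence_class_histogram <- function(counts) {
  counts <- counts[counts >= 1]
  if (!length(counts)) stop("no species with at least one occurrence")
  n <- length(counts)
  c(
    one = sum(counts == 1) / n,
    few = sum(counts >= 2 & counts <= 19) / n,
    many = sum(counts >= 20) / n
  )
}

#' Occurrence-weighted mean taxonomic precision
#'
#' @param summaries a per-taxon summary table with columns `taxon`,
#'   `nb_occ`, `precision`.
#' @param exclude taxa to leave out (e.g. `"Aves"`).
#' @return the weighted proportion `sum(nb_occ * precision) / sum(nb_occ)`.
#' @export
weighted_precision <- function(summaries, exclude = character()) {
  s <- as.data.table(summaries)
  s <- s[!s[["taxon"]] %in% exclude]
  if (nrow(s) == 0L) stop("no taxa left after exclusion")
  sum(s$nb_occ * s$precision) / sum(s$nb_occ)
}

#' Share of a reference total held by one taxon
#'
#' @param summaries per-taxon summary table (`taxon`, and the `column` to
#'   share).
#' @param taxon the focal taxon.
#' @param reference_total the denominator (e.g. the full-portal occurrence
#'   count).
#' @param column which column to take the numerator from (default
#'   `"nb_occ"`).
#' @return proportion in \[0, 1\].
#' @export
share_of_total <- function(summaries, taxon, reference_total,
                           column = "nb_occ") {
  s <- as.data.table(summaries)
  wanted <- s[["taxon"]] == taxon
  row <- s[wanted]
  if (nrow(row) != 1L) stop("taxon '", taxon, "' not found exactly once")
  as.numeric(row[[column]]) / reference_total
}
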