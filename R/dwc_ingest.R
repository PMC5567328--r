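#' @importFrom data.table data.table fread fwrite setnames as.data.table copy
#'   setorder setorderv setattr rbindlist := .N .SD
#' @importFrom stats median mad quantile coef rnorm runif rbinom rpois rnbinom
#'   rlnorm rgeom rmultinom setNames lm pnorm complete.cases
#' @importFrom utils head read.delim
NULL

# Controlled vocabularies for the basisOfRecord -> origin mapping.
# Specimen-like bases: fossils, living specimens, material samples, preserved
# specimens.  Observation-like bases: human/machine observations, generic
# observation, literature.  Everything else (incl. empty, "UNKNOWN") -> Unknown.
.basis_specimen <- c(
  "fossilspecimen", "livingspecimen", "materialsample", "preservedspecimen"
)
.basis_observation <- c(
  "humanobservation", "machineobservation", "observation", "literature"
)

#' Classify a raw basisOfRecord value into a data-origin category
#'
#' Occurrence records derive either from a physical object (a preserved,
#' living or fossil specimen, or a material sample), from an observation
#' event (human, machine, undifferentiated, or literature-derived), or carry
#' no usable basis.  Matching is case-insensitive and ignores space,
#' underscore and hyphen separators, so `"PRESERVED_SPECIMEN"`,
#' `"preservedSpecimen"` and `"Preserved specimen"` are equivalent.
#'
#' @param basis_raw character vector of raw `basisOfRecord` values; `NA` and
#'   empty strings are allowed.
#' @return factor vector with levels `Specimen`, `Observation`, `Unknown`.
#' @examples
#' classify_basis(c("PRESERVED_SPECIMEN", "HUMAN_OBSERVATION", "", "whatever"))
#' @export
classify_basis <- function(basis_raw) {
  key <- gsub("[ _-]", "", tolower(as.character(basis_raw)))
  out <- rep("Unknown", length(key))
  out[key %in% .basis_specimen] <- "Specimen"
  out[key %in% .basis_observation] <- "Observation"
  factor(out, levels = c("Specimen", "Observation", "Unknown"))
}

#' Flag temporal and spatial completeness of occurrence records
#'
#' A record has a temporal issue when its month, year or both are missing,
#' and a spatial issue when coordinates are missing or the record is flagged
#' as having geospatial issues.
#'
#' @param year,month integer vectors (NA = absent).
#' @param lat,lon numeric coordinate vectors (NA = absent).
#' @param geo_issue logical vector: record flagged with a geospatial issue.
#' @return a list with logical vectors `time_issue` and `space_issue`.
#' @export
flag_completeness <- function(year, month, lat, lon, geo_issue) {
  list(
    time_issue = is.na(year) | is.na(month),
    space_issue = is.na(lat) | is.na(lon) | (!is.na(geo_issue) & geo_issue)
  )
}

# Ranks counting as "species level or lower".
.precise_ranks <- c("species", "subspecies", "variety", "form")

#' Flag taxonomic precision of an identification
#'
#' An occurrence is taxonomically precise when it is identified to species
#' rank or lower (species, subspecies, variety, form) and carries a
#' non-empty species name.
#'
#' @param taxon_rank character vector of rank labels (case-insensitive).
#' @param species character vector of species names ("" or NA = absent).
#' @return logical vector.
#' @export
flag_precision <- function(taxon_rank, species) {
  rank_ok <- tolower(trimws(as.character(taxon_rank))) %in% .precise_ranks
  rank_ok & !is.na(species) & nzchar(trimws(as.character(species)))
}

#' Count known species of a class in a taxonomic backbone
#'
#' Known species richness N is the number of distinct species names carrying
#' the accepted or doubtful taxonomic status; synonyms are excluded.
#'
#' @param backbone a backbone table as returned by [read_backbone()] or
#'   [gen_backbone()] (columns `species`, `class_name`, `status`).
#' @param class_name the class to count; omit to count all classes at once.
#' @return if `class_name` is given, a single integer (0 with a warning when
#'   the class is absent); otherwise a named integer vector per class.
#' @export
count_known_species <- function(backbone, class_name = NULL) {
  bb <- as.data.table(backbone)
  bb <- bb[status %in% c("accepted", "doubtful")]
  if (is.null(class_name)) {
    n <- bb[, .(N = length(unique(species))), by = class_name]
    return(setNames(as.integer(n$N), n$class_name))
  }
  wanted <- bb[["class_name"]] == class_name  # evaluate outside [ to avoid
  sub <- bb[wanted]                           # column-name shadowing
  if (nrow(sub) == 0L) {
    warning("class '", class_name, "' absent from backbone; N = 0")
    return(0L)
  }
  length(unique(sub$species))
}

# Default schema: Darwin Core term -> internal column.
default_schema <- function() {
  c(
    scientificName = "species", taxonRank = "taxon_rank", class = "class_name",
    order = "order_name", year = "year", month = "month",
    decimalLatitude = "lat", decimalLongitude = "lon",
    basisOfRecord = "basis", issue = "issue"
  )
}

# Lenient numeric parsing: anything unparseable becomes NA (absent), and is
# counted rather than causing row rejection.
.num_or_na <- function(x) suppressWarnings(as.numeric(as.character(x)))
.int_or_na <- function(x) {
  v <- suppressWarnings(as.numeric(as.character(x)))
  v[!is.finite(v)] <- NA_real_
  as.integer(round(v))
}

#' Normalize a raw occurrence table into the pipeline record model
#'
#' Derives the origin category, completeness flags and taxonomic-precision
#' flag, normalizes longitudes to \[-180, 180), blanks species names on
#' imprecise records (so `species != "" <=> species_precise`), and treats
#' unparseable year/month/coordinate values as absent rather than dropping
#' the row.  Out-of-range latitudes are treated as absent coordinates.
#'
#' @param raw a data.frame/data.table with internal column names (see
#'   [read_occurrences()] for file input).
#' @return a `data.table` of normalized records with attribute `tallies`,
#'   a named integer vector of lenient-parsing counts.
#' @export
normalize_occurrences <- function(raw) {
  dt <- as.data.table(raw)
  need <- c("class_name", "basis")
  miss <- setdiff(need, names(dt))
  if (length(miss)) {
    stop("missing mandatory columns: ", paste(miss, collapse = ", "))
  }
  for (col in c("order_name", "species", "taxon_rank", "issue")) {
    if (!col %in% names(dt)) dt[[col]] <- ""
  }
  for (col in c("year", "month", "lat", "lon")) {
    if (!col %in% names(dt)) dt[[col]] <- NA
  }
  n_raw_year <- sum(!is.na(dt$year) & nzchar(as.character(dt$year)))
  dt[, year := .int_or_na(year)]
  dt[, month := .int_or_na(month)]
  dt[!is.na(month) & (month < 1L | month > 12L), month := NA_integer_]
  dt[, lat := .num_or_na(lat)]
  dt[, lon := .num_or_na(lon)]
  bad_year <- n_raw_year - sum(!is.na(dt$year))
  # out-of-range coordinates are unusable -> absent
  bad_coord <- sum((!is.na(dt$lat) & abs(dt$lat) > 90), na.rm = TRUE)
  dt[!is.na(lat) & abs(lat) > 90, c("lat", "lon") := .(NA_real_, NA_real_)]
  dt[!is.na(lon), lon := ((lon + 180) %% 360) - 180]
  dt[, species := trimws(ifelse(is.na(species), "", as.character(species)))]
  dt[, issue := ifelse(is.na(issue), "", as.character(issue))]
  dt[, geo_issue := nzchar(trimws(issue))]
  dt[, origin := classify_basis(basis)]
  dt[, species_precise := flag_precision(taxon_rank, species)]
  dt[species_precise == FALSE, species := ""]
  fl <- flag_completeness(dt$year, dt$month, dt$lat, dt$lon, dt$geo_issue)
  dt[, time_issue := fl$time_issue]
  dt[, space_issue := fl$space_issue]
  dt[, class_name := ifelse(is.na(class_name), "", trimws(as.character(class_name)))]
  dt[, order_name := ifelse(is.na(order_name), "", trimws(as.character(order_name)))]
  tallies <- c(
    badYear = as.integer(bad_year),
    badCoord = as.integer(bad_coord),
    noClass = sum(!nzchar(dt$class_name))
  )
  setattr(dt, "tallies", tallies)
  dt[]
}

#' Read an occurrence table in the tab-separated Darwin Core dialect
#'
#' Expects a UTF-8 tab-separated file with a header row of Darwin Core term
#' names.  The header-to-field mapping is configurable to tolerate dialect
#' variants.  Unparseable field values are mapped to absent (triggering the
#' corresponding issue flag) and tallied, never silently dropped; only rows
#' with the wrong column count are skipped (and tallied).
#'
#' @param path file path.
#' @param schema named character vector mapping file headers to internal
#'   fields; default [default_schema()].
#' @return normalized record `data.table` (see [normalize_occurrences()]),
#'   with a `tallies` attribute including `badRow` skip counts.
#' @export
read_occurrences <- function(path, schema = default_schema()) {
  raw <- fread(
    path, sep = "\t", header = TRUE, colClasses = "character",
    fill = TRUE, quote = "", na.strings = NULL, showProgress = FALSE
  )
  mandatory <- names(schema)[schema %in% c("class_name", "basis")]
  miss <- setdiff(mandatory, names(raw))
  if (length(miss)) {
    stop("occurrence file is missing mandatory headers: ",
         paste(miss, collapse = ", "))
  }
  keep <- intersect(names(raw), names(schema))
  raw <- raw[, ..keep]
  setnames(raw, keep, unname(schema[keep]))
  out <- normalize_occurrences(raw)
  setattr(out, "tallies", c(attr(out, "tallies"), badRow = 0L))
  out
}

#' Read a taxonomic backbone table
#'
#' Tab-separated with headers `scientificName`, `class`, `order`,
#' `taxonomicStatus`; status values outside accepted/doubtful/synonym are
#' kept verbatim but never counted as known species.
#'
#' @param path file path.
#' @return `data.table` with columns `species`, `class_name`, `order_name`,
#'   `status`.
#' @export
read_backbone <- function(path) {
  raw <- fread(path, sep = "\t", header = TRUE, colClasses = "character",
               quote = "", na.strings = NULL, showProgress = FALSE)
  need <- c("scientificName", "class", "taxonomicStatus")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("backbone file is missing mandatory headers: ",
         paste(miss, collapse = ", "))
  }
  if (!"order" %in% names(raw)) raw[["order"]] <- ""
  out <- data.table(
    species = trimws(raw$scientificName),
    class_name = trimws(raw$class),
    order_name = trimws(raw$order),
    status = tolower(trimws(raw$taxonomicStatus))
  )
  out[nzchar(species)]
}

#' Write occurrence records in the tab-separated Darwin Core dialect
#'
#' Inverse of [read_occurrences()]: flags are not serialized (they are
#' re-derived on read), so a write/read round trip preserves them.
#'
#' @param records normalized record table.
#' @param path output file path.
#' @export
write_occurrences <- function(records, path) {
  dt <- as.data.table(records)
  out <- data.table(
    scientificName = dt$species,
    taxonRank = dt$taxon_rank,
    class = dt$class_name,
    order = dt$order_name,
    year = dt$year,
    month = dt$month,
    decimalLatitude = dt$lat,
    decimalLongitude = dt$lon,
    basisOfRecord = dt$basis,
    issue = dt$issue
  )
  fwrite(out, path, sep = "\t", quote = FALSE, na = "")
  invisible(path)
}

#' Write a backbone table in the tab-separated dialect
#' @param backbone backbone table (`species`, `class_name`, `order_name`,
#'   `status`).
#' @param path output file path.
#' @export
write_backbone <- function(backbone, path) {
  dt <- as.data.table(backbone)
  out <- data.table(
    scientificName = dt$species, class = dt$class_name,
    order = dt$order_name, taxonomicStatus = dt$status
  )
  fwrite(out, path, sep = "\t", quote = FALSE, na = "")
  invisible(path)
}
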