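# Multiple correspondence analysis of categorical occurrence attributes
# (class, year bin, data origin, data completeness), with rare-category
# ventilation, computed as correspondence analysis of the complete
# disjunctive (indicator) table.

#' Year bins used in the record-quality MCA
#' @export
YEAR_BINS <- c(
  "<1900", "1900-1949", "1950-1974", "1975-1999", "2000-2004",
  "2005-2009", "2010-2014", ">=2015", "Unknown Year"
)

#' Bin record years into the MCA age categories
#'
#' Eight calendar intervals plus an `Unknown Year` category for records with
#' a temporal issue (missing year or month).
#'
#' @param year integer vector (NA = unknown).
#' @param time_issue logical; records with a temporal issue are binned as
#'   `Unknown Year` regardless of any partial year value.
#' @return factor with levels [YEAR_BINS].
#' @export
bin_year <- function(year, time_issue = is.na(year)) {
  out <- rep("Unknown Year", length(year))
  y <- year
  known <- !time_issue & !is.na(y)
  brk <- c(-Inf, 1899, 1949, 1974, 1999, 2004, 2009, 2014, Inf)
  lab <- YEAR_BINS[1:8]
  out[known] <- as.character(cut(y[known], breaks = brk, labels = lab))
  factor(out, levels = YEAR_BINS)
}

#' Completeness category of a record
#' @param time_issue,space_issue logical flags.
#' @return factor over `No issue`, `Temporal issue`, `Spatial issues`,
#'   `Both issues`.
#' @export
completeness_category <- function(time_issue, space_issue) {
  out <- ifelse(
    time_issue & space_issue, "Both issues",
    ifelse(time_issue, "Temporal issue",
           ifelse(space_issue, "Spatial issues", "No issue"))
  )
  factor(out, levels = c("No issue", "Temporal issue", "Spatial issues",
                         "Both issues"))
}

#' Build the MCA input table from normalized occurrence records
#'
#' Active variables: `class` (one category per class), `year_bin` (eight
#' intervals plus Unknown Year), `origin` (Specimen/Observation/Unknown)
#' and `completeness` (four categories).  A uniform random subsample
#' without replacement of `sample_size` rows is drawn when the table is
#' larger; otherwise all rows are used with a message.
#'
#' @param records normalized occurrence table (class-affiliated records
#'   only are used).
#' @param sample_size rows to sample (default all).
#' @param seed RNG seed for the subsample.
#' @return `data.frame` of factors, one row per sampled occurrence.
#' @export
mca_table <- function(records, sample_size = NULL, seed = 1L) {
  dt <- as.data.table(records)[nzchar(class_name)]
  tab <- data.frame(
    class = factor(dt$class_name),
    year_bin = bin_year(dt$year, dt$time_issue),
    origin = factor(dt$origin, levels = c("Specimen", "Observation", "Unknown")),
    completeness = completeness_category(dt$time_issue, dt$space_issue)
  )
  if (!is.null(sample_size)) {
    if (sample_size >= nrow(tab)) {
      if (sample_size > nrow(tab)) {
        message("sample_size ", sample_size, " > ", nrow(tab),
                " rows; using all rows")
      }
    } else {
      set.seed(seed)
      tab <- tab[sample.int(nrow(tab), sample_size), , drop = FALSE]
      rownames(tab) <- NULL
    }
  }
  tab
}

#' Ventilate rare categories of a categorical table
#'
#' Categories observed in less than `threshold` of the rows have their rows
#' randomly reassigned among the variable's remaining categories, with
#' probabilities proportional to those categories' frequencies; the process
#' repeats until no category is below threshold or a single category
#' remains, in which case the variable is constant and is dropped with a
#' warning.
#'
#' @param table data.frame of factors.
#' @param threshold minimum category share (default 0.005 = 0.5%).
#' @param seed RNG seed for the reassignments.
#' @return data.frame with identical row count; dropped factor levels are
#'   removed.
#' @export
ventilate <- function(table, threshold = 0.005, seed = 1L) {
  set.seed(seed)
  out <- table
  drop_vars <- character()
  for (v in names(out)) {
    x <- factor(out[[v]])  # refresh levels
    repeat {
      x <- droplevels(x)
      freq <- table(x) / length(x)
      rare <- names(freq)[freq < threshold]
      if (length(rare) == 0L) break
      keep <- setdiff(levels(x), rare)
      if (length(keep) <= 1L) {
        if (length(keep) == 1L) x[] <- keep[1]
        drop_vars <- c(drop_vars, v)
        break
      }
      w <- as.numeric(freq[keep])
      idx <- which(x %in% rare)
      x[idx] <- sample(keep, length(idx), replace = TRUE, prob = w / sum(w))
    }
    out[[v]] <- droplevels(x)
  }
  if (length(drop_vars)) {
    warning("variable(s) collapsed to a single category and dropped: ",
            paste(drop_vars, collapse = ", "))
    out <- out[, setdiff(names(out), drop_vars), drop = FALSE]
  }
  out
}

#' Fit a multiple correspondence analysis
#'
#' Correspondence analysis of the complete disjunctive (indicator) coding:
#' the indicator matrix is converted to a correspondence table, centred and
#' scaled by row/column masses, and the standardized residuals are
#' decomposed by SVD.  Axis orientation is fixed by making the
#' largest-magnitude category loading on each axis positive, so results are
#' deterministic.
#'
#' @param table data.frame of factor variables (>= 2 levels each; constant
#'   variables are an error - ventilate or drop them first).
#' @param n_axes number of axes to retain (default `min(J - Q, 10)` where
#'   J = total categories, Q = number of variables).
#' @return an object of class `occbias_mca`: list with `eigenvalues`,
#'   `inertia_share`, `col_coords` (principal category coordinates),
#'   `row_coords` (principal row scores), `J`, `Q`, `n` and the category
#'   bookkeeping.
#' @export
fit_mca <- function(table, n_axes = NULL) {
  table <- as.data.frame(table)
  facs <- lapply(table, function(x) droplevels(factor(x)))
  nlev <- vapply(facs, nlevels, 1L)
  if (any(nlev < 2L)) {
    stop("constant variable(s): ", paste(names(facs)[nlev < 2L], collapse = ", "),
         "; ventilate or drop them before fitting")
  }
  n <- nrow(table); Q <- length(facs); J <- sum(nlev)
  # indicator matrix
  Z <- do.call(cbind, lapply(names(facs), function(v) {
    m <- stats::model.matrix(~ x - 1, data = data.frame(x = facs[[v]]))
    colnames(m) <- paste(v, levels(facs[[v]]), sep = ".")
    m
  }))
  P <- Z / (n * Q)
  r <- rowSums(P)            # 1/n each
  cm <- colSums(P)           # category masses
  S <- (P - outer(r, cm)) / sqrt(outer(r, cm))
  sv <- svd(S)
  k_max <- min(J - Q, length(sv$d))
  if (is.null(n_axes)) n_axes <- min(k_max, 10L)
  n_axes <- min(n_axes, k_max)
  d <- sv$d[seq_len(n_axes)]
  U <- sv$u[, seq_len(n_axes), drop = FALSE]
  V <- sv$v[, seq_len(n_axes), drop = FALSE]
  # principal coordinates
  row_coords <- sweep(U / sqrt(r), 2, d, `*`)
  col_coords <- sweep(V / sqrt(cm), 2, d, `*`)
  # deterministic orientation: largest |loading| per axis made positive
  for (k in seq_len(n_axes)) {
    j <- which.max(abs(col_coords[, k]))
    if (col_coords[j, k] < 0) {
      col_coords[, k] <- -col_coords[, k]
      row_coords[, k] <- -row_coords[, k]
    }
  }
  rownames(col_coords) <- colnames(Z)
  eig <- d^2
  structure(list(
    eigenvalues = eig,
    total_inertia = J / Q - 1,
    inertia_share = eig / (J / Q - 1),
    col_coords = col_coords,
    row_coords = row_coords,
    J = J, Q = Q, n = n,
    variables = names(facs),
    category_masses = cm
  ), class = "occbias_mca")
}

#' @export
print.occbias_mca <- function(x, ...) {
  cat("Multiple correspondence analysis:", x$n, "rows,", x$Q,
      "variables,", x$J, "categories\n")
  cat("First eigenvalues:", round(head(x$eigenvalues, 5), 4), "\n")
  cat("Inertia share (axis 1, 2):",
      round(x$inertia_share[seq_len(min(2, length(x$inertia_share)))], 4), "\n")
  invisible(x)
}

#' Class barycentres on the MCA axes
#'
#' The barycentre of a class is the mean of its occurrences' row scores:
#' the average position of the class occurrences in the factorial plane.
#'
#' @param fit an `occbias_mca` object.
#' @param classes factor/character vector of class labels, one per row of
#'   the fitted table (in the same order).
#' @param axes which axes to report (default 1:2).
#' @return `data.table` with `taxon` and one column per axis.
#' @export
class_barycentres <- function(fit, classes, axes = 1:2) {
  stopifnot(length(classes) == nrow(fit$row_coords))
  axes <- axes[axes <= ncol(fit$row_coords)]
  sc <- fit$row_coords[, axes, drop = FALSE]
  dt <- data.table(taxon = as.character(classes), sc)
  setnames(dt, c("taxon", paste0("axis", axes)))
  dt[, lapply(.SD, mean), by = taxon]
}
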