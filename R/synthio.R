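# Seeded generator of taxonomic backbones, occurrence tables and covariate
# tables with the statistical structure the audit stages assume: a few
# classes with heavy-tailed per-species abundances, controllable taxonomic
# precision, origin mixes, temporal/spatial missingness, recency-weighted
# collection years, spatially clustered coordinates, and covariates coupled
# to occurrence counts through a known negative-binomial regression.

#' Build and validate a synthetic-data configuration
#'
#' Defaults describe a desk-scale analogue of a large occurrence snapshot:
#' six classes spanning the observed regimes (a bird-like class dominating
#' the record stream with high precision and observation-based records; a
#' large plant class; a very speciose, under-recorded insect class; a
#' mammal-like class; a specimen-heavy mollusc class with high missingness;
#' a small amphibian-like class), lognormal(0, 2) per-species abundances,
#' years 1900-2016 with exponential recency growth, and 3 Gaussian
#' coordinate clusters per species.
#'
#' @param seed integer master seed; fixes every draw.
#' @param n_occurrences total records to generate.
#' @param classes data.frame with columns `class_name`, `N` (known species),
#'   `weight` (occurrence share), `precision_rate`, `o_spec`, `o_obs`,
#'   `o_unk`, `missing_time_rate`, `missing_space_rate`.
#' @param abundance_model `"lognormal"` or `"geometric"`.
#' @param abundance_pars parameters: `meanlog`/`sdlog` or `prob`.
#' @param year_range calendar span of collection years.
#' @param year_growth exponential recency-growth rate per year (0 =
#'   uniform).
#' @param n_clusters,cluster_sd spatial model: cluster centres per species
#'   and Gaussian dispersion in degrees.
#' @param geo_issue_rate share of coordinate-bearing records flagged with a
#'   geospatial issue.
#' @param synonym_fraction extra synonym backbone entries per known
#'   species.
#' @param orders_per_class orders each class's species are spread over.
#' @param glm_truth coefficients `(b0, b1, b2, b3)` and NB dispersion `k`
#'   of the covariate-coupled occurrence model (log link, log1p-transformed
#'   covariates).
#' @return validated list of class `synth_config`.
#' @export
synth_config <- function(
    seed = 1L,
    n_occurrences = 20000L,
    classes = NULL,
    abundance_model = c("lognormal", "geometric"),
    abundance_pars = list(meanlog = 0, sdlog = 2, prob = 0.1),
    year_range = c(1900L, 2016L),
    year_growth = 0.03,
    n_clusters = 3L,
    cluster_sd = 2,
    geo_issue_rate = 0.01,
    synonym_fraction = 0.2,
    orders_per_class = 4L,
    glm_truth = list(b0 = 3, b1 = 0.8, b2 = 0, b3 = 0, k = 1)) {
  abundance_model <- match.arg(abundance_model)
  if (is.null(classes)) {
    classes <- data.frame(
      class_name = c("Avesia", "Magnolioid", "Insectia",
                     "Mammaloid", "Gastropodia", "Amphibioid"),
      N = c(1000L, 20000L, 30000L, 1200L, 8000L, 600L),
      weight = c(0.53, 0.19, 0.08, 0.09, 0.05, 0.06),
      precision_rate = c(0.99, 0.92, 0.77, 0.88, 0.69, 0.91),
      o_spec = c(0.05, 0.55, 0.50, 0.70, 0.80, 0.75),
      o_obs = c(0.94, 0.40, 0.45, 0.25, 0.10, 0.20),
      o_unk = c(0.01, 0.05, 0.05, 0.05, 0.10, 0.05),
      missing_time_rate = c(0.02, 0.15, 0.20, 0.25, 0.55, 0.35),
      missing_space_rate = c(0.02, 0.20, 0.25, 0.30, 0.48, 0.40)
    )
  }
  cfg <- list(
    seed = as.integer(seed), n_occurrences = as.integer(n_occurrences),
    classes = as.data.frame(classes), abundance_model = abundance_model,
    abundance_pars = abundance_pars, year_range = as.integer(year_range),
    year_growth = year_growth, n_clusters = as.integer(n_clusters),
    cluster_sd = cluster_sd, geo_issue_rate = geo_issue_rate,
    synonym_fraction = synonym_fraction,
    orders_per_class = as.integer(orders_per_class), glm_truth = glm_truth
  )
  validate_synth_config(cfg)
  class(cfg) <- "synth_config"
  cfg
}

validate_synth_config <- function(cfg) {
  cls <- cfg$classes
  need <- c("class_name", "N", "weight", "precision_rate", "o_spec",
            "o_obs", "o_unk", "missing_time_rate", "missing_space_rate")
  miss <- setdiff(need, names(cls))
  if (length(miss)) stop("configuration error: classes missing field(s) ",
                         paste(miss, collapse = ", "))
  if (any(cls$N < 1)) stop("configuration error: N must be >= 1 per class")
  probs <- c(cls$precision_rate, cls$missing_time_rate,
             cls$missing_space_rate, cfg$geo_issue_rate,
             cfg$synonym_fraction)
  if (any(probs < 0 | probs > 1)) {
    stop("configuration error: a rate lies outside [0, 1]")
  }
  mix <- cls$o_spec + cls$o_obs + cls$o_unk
  if (any(abs(mix - 1) > 1e-9)) {
    stop("configuration error: origin_mix must sum to 1 (off by ",
         max(abs(mix - 1)), ")")
  }
  if (any(cls$weight < 0) || abs(sum(cls$weight) - 1) > 1e-9) {
    stop("configuration error: weight must be a probability vector")
  }
  if (cfg$n_occurrences < 1) stop("configuration error: n_occurrences < 1")
  gt <- cfg$glm_truth
  if (!all(c("b0", "b1", "b2", "b3", "k") %in% names(gt))) {
    stop("configuration error: glm_truth needs b0, b1, b2, b3, k")
  }
  if (gt$k <= 0) stop("configuration error: glm_truth$k must be > 0")
  invisible(TRUE)
}

# Species name factory: unique binomials per class.
.species_names <- function(class_name, n) {
  sprintf("%s species%04d", sub(" .*", "", class_name), seq_len(n))
}

#' Generate a synthetic taxonomic backbone
#'
#' Per class: exactly `N` entries with accepted or doubtful status (about
#' 10% doubtful) spread over `orders_per_class` orders, plus
#' `round(synonym_fraction * N)` synonym entries pointing at accepted
#' names; all names unique.
#'
#' @param config a [synth_config()].
#' @return backbone `data.table` (`species`, `class_name`, `order_name`,
#'   `status`, `accepted_species`).
#' @export
gen_backbone <- function(config) {
  validate_synth_config(config)
  set.seed(config$seed)
  out <- lapply(seq_len(nrow(config$classes)), function(i) {
    cl <- config$classes[i, ]
    nm <- .species_names(cl$class_name, cl$N)
    orders <- sprintf("%s order%02d", sub(" .*", "", cl$class_name),
                      seq_len(config$orders_per_class))
    ord <- sample(orders, cl$N, replace = TRUE)
    status <- sample(c("accepted", "doubtful"), cl$N, replace = TRUE,
                     prob = c(0.9, 0.1))
    main <- data.table(species = nm, class_name = cl$class_name,
                       order_name = ord, status = status,
                       accepted_species = nm)
    n_syn <- round(config$synonym_fraction * cl$N)
    if (n_syn > 0) {
      acc <- main[status == "accepted"]
      tgt <- acc[sample(.N, n_syn, replace = TRUE)]
      syn <- data.table(
        species = sprintf("%s syn%04d", sub(" .*", "", cl$class_name),
                          seq_len(n_syn)),
        class_name = cl$class_name, order_name = tgt$order_name,
        status = "synonym", accepted_species = tgt$species
      )
      main <- rbind(main, syn)
    }
    main
  })
  rbindlist(out)
}

# Per-species abundance weights under the configured model.
.abundance_draw <- function(config, n) {
  p <- config$abundance_pars
  if (config$abundance_model == "lognormal") {
    rlnorm(n, meanlog = p$meanlog, sdlog = p$sdlog)
  } else {
    rgeom(n, prob = p$prob) + 1
  }
}

#' Generate a synthetic occurrence table
#'
#' Class totals are multinomial in the configured weights; within a class,
#' records are multinomially allocated to species proportionally to
#' heavy-tailed abundance draws, so class totals stay exactly controllable.
#' Each record then receives: a precise species identification with the
#' class's precision rate (otherwise genus rank with a blanked name), an
#' origin category from the class mix, a collection year from the
#' recency-growth law (dropped, with the month, at the missing-time rate),
#' and coordinates from one of the species' Gaussian clusters (dropped at
#' the missing-space rate; flagged with a geospatial issue at
#' `geo_issue_rate`).  Synonym names are never emitted.
#'
#' @param config a [synth_config()].
#' @param backbone backbone from [gen_backbone()].
#' @return normalized occurrence `data.table` (same model as
#'   [normalize_occurrences()]) with attribute `truth`: the generator's own
#'   bookkeeping of per-class origin and missingness tallies.
#' @export
gen_occurrences <- function(config, backbone) {
  validate_synth_config(config)
  bb <- as.data.table(backbone)
  if (nrow(bb) == 0L) stop("empty backbone")
  set.seed(config$seed + 1L)
  cls <- config$classes
  n_per_class <- as.integer(rmultinom(1, config$n_occurrences, cls$weight))
  years <- seq(config$year_range[1], config$year_range[2])
  yw <- exp(config$year_growth * (years - years[1]))
  recs <- vector("list", nrow(cls))
  truth <- vector("list", nrow(cls))
  for (i in seq_len(nrow(cls))) {
    cl <- cls[i, ]
    n <- n_per_class[i]
    if (n == 0L) next
    pool <- bb[class_name == cl$class_name & status != "synonym"]
    ab <- .abundance_draw(config, nrow(pool))
    sp_n <- as.integer(rmultinom(1, n, ab / sum(ab)))
    idx <- rep.int(seq_len(nrow(pool)), sp_n)
    sp <- pool$species[idx]
    ord <- pool$order_name[idx]
    precise <- runif(n) < cl$precision_rate
    origin <- sample(c("Specimen", "Observation", "Unknown"), n,
                     replace = TRUE, prob = c(cl$o_spec, cl$o_obs, cl$o_unk))
    t_miss <- runif(n) < cl$missing_time_rate
    s_miss <- runif(n) < cl$missing_space_rate
    year <- sample(years, n, replace = TRUE, prob = yw / sum(yw))
    month <- sample.int(12L, n, replace = TRUE)
    year[t_miss] <- NA_integer_; month[t_miss] <- NA_integer_
    # per-species cluster centres, drawn lazily for the species present
    usp <- unique(idx)
    centres <- data.table(
      sp_i = rep(usp, each = config$n_clusters),
      c_lat = runif(length(usp) * config$n_clusters, -60, 60),
      c_lon = runif(length(usp) * config$n_clusters, -180, 180)
    )
    pick <- centres[
      sample.int(config$n_clusters, n, replace = TRUE) +
        (match(idx, usp) - 1L) * config$n_clusters]
    lat <- pmin(pmax(pick$c_lat + rnorm(n, 0, config$cluster_sd), -90), 90)
    lon <- ((pick$c_lon + rnorm(n, 0, config$cluster_sd) + 180) %% 360) - 180
    lat[s_miss] <- NA_real_; lon[s_miss] <- NA_real_
    g_iss <- !s_miss & runif(n) < config$geo_issue_rate
    recs[[i]] <- data.table(
      species = ifelse(precise, sp, ""),
      taxon_rank = ifelse(precise, "SPECIES", "GENUS"),
      class_name = cl$class_name, order_name = ord,
      year = year, month = month, lat = lat, lon = lon,
      basis = c(Specimen = "PRESERVED_SPECIMEN",
                Observation = "HUMAN_OBSERVATION",
                Unknown = "UNKNOWN")[origin],
      issue = ifelse(g_iss, "GEOSPATIAL_ISSUE", "")
    )
    truth[[i]] <- data.table(
      class_name = cl$class_name, n = n,
      n_spec = sum(origin == "Specimen"),
      n_obs = sum(origin == "Observation"),
      n_unk = sum(origin == "Unknown"),
      n_time_missing = sum(t_miss),
      n_space_issue = sum(s_miss | g_iss),
      n_precise = sum(precise)
    )
  }
  out <- normalize_occurrences(rbindlist(recs))
  setattr(out, "truth", rbindlist(truth))
  out
}

#' Generate per-species covariate tables
#'
#' `coupled` mode draws public-interest counts per species and
#' research-effort counts per order, then draws each species' occurrence
#' total from a negative binomial with mean
#' `exp(b0 + b1*t(x_I) + b2*t(x_R) + b3*t(x_I)*t(x_R))` (t = log1p) and
#' dispersion `k`, so the model stage can recover the truth.
#' `independent` mode draws covariates with zero true effect (occurrence
#' totals from an NB independent of the covariates) for type-I-error
#' testing.
#'
#' @param config a [synth_config()].
#' @param backbone backbone from [gen_backbone()].
#' @param mode `"coupled"` or `"independent"`.
#' @param n_species species to draw per class (default: all accepted/
#'   doubtful backbone species).
#' @return covariate `data.table` (`species`, `class_name`, `order_name`,
#'   `interest_plain`, `interest`, `research`, `n_occ`), with attribute
#'   `truth` (a `CovariateTruth` table with `expected_occurrences`) in
#'   coupled mode.
#' @export
gen_covariates <- function(config, backbone, mode = c("coupled", "independent"),
                           n_species = NULL) {
  mode <- match.arg(mode)
  validate_synth_config(config)
  bb <- as.data.table(backbone)[status != "synonym"]
  if (nrow(bb) == 0L) stop("empty backbone")
  set.seed(config$seed + 2L)
  if (!is.null(n_species)) {
    bb <- bb[, head(.SD, n_species), by = class_name]
  }
  gt <- config$glm_truth
  # interest: heavy-tailed web-page counts; research: one draw per order
  interest <- as.integer(round(rlnorm(nrow(bb), meanlog = 5, sdlog = 2)))
  orders <- unique(bb$order_name)
  research_by_order <- setNames(
    as.integer(round(rlnorm(length(orders), meanlog = 5, sdlog = 1.5))),
    orders
  )
  research <- research_by_order[bb$order_name]
  ti <- log1p(interest); tr <- log1p(research)
  if (mode == "coupled") {
    mu <- exp(gt$b0 + gt$b1 * ti + gt$b2 * tr + gt$b3 * ti * tr)
    n_occ <- rnbinom(nrow(bb), size = gt$k, mu = mu)
  } else {
    mu <- rep(exp(gt$b0), nrow(bb))
    n_occ <- rnbinom(nrow(bb), size = gt$k, mu = mu)
  }
  out <- data.table(
    species = bb$species, class_name = bb$class_name,
    order_name = bb$order_name,
    interest_plain = pmax(0L, as.integer(round(interest * runif(nrow(bb), 0.3, 0.8)))),
    interest = interest, research = as.integer(research),
    n_occ = as.integer(n_occ)
  )
  if (mode == "coupled") {
    setattr(out, "truth", data.table(
      species = bb$species, interest = interest,
      research = as.integer(research), expected_occurrences = mu
    ))
  }
  out
}

#' Write a covariate table in the tab-separated dialect
#' @param cov covariate table from [gen_covariates()].
#' @param path output file path.
#' @export
write_covariates <- function(cov, path) {
  dt <- as.data.table(cov)
  out <- data.table(
    species = dt$species, class = dt$class_name, order = dt$order_name,
    interest_plain = dt$interest_plain, interest_keyword = dt$interest,
    research = dt$research, n_occ = dt$n_occ
  )
  fwrite(out, path, sep = "\t", quote = FALSE, na = "")
  invisible(path)
}

#' Read a covariate table written by [write_covariates()]
#' @param path file path.
#' @return covariate `data.table` with internal column names.
#' @export
read_covariates <- function(path) {
  raw <- fread(path, sep = "\t", header = TRUE, showProgress = FALSE)
  need <- c("species", "class", "interest_keyword", "research", "n_occ")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("covariate file missing headers: ",
                         paste(miss, collapse = ", "))
  data.table(
    species = as.character(raw$species),
    class_name = as.character(raw$class),
    order_name = if ("order" %in% names(raw)) as.character(raw$order) else "",
    interest_plain = if ("interest_plain" %in% names(raw))
      as.integer(raw$interest_plain) else NA_integer_,
    interest = as.integer(raw$interest_keyword),
    research = as.integer(raw$research),
    n_occ = as.integer(raw$n_occ)
  )
}
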