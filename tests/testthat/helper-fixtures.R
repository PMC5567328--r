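# Shared fixtures: tiny in-code occurrence tables and small synthetic
# configurations used across test files.

# A raw occurrence table in internal column names, ready for
# normalize_occurrences(); defaults give a complete, precise record.
raw_occ <- function(n = 1, species = "Corvus corax", taxon_rank = "SPECIES",
                    class_name = "Aves", order_name = "Passeriformes",
                    year = 2000L, month = 6L, lat = 45, lon = 10,
                    basis = "HUMAN_OBSERVATION", issue = "") {
  data.frame(
    species = rep_len(species, n), taxon_rank = rep_len(taxon_rank, n),
    class_name = rep_len(class_name, n), order_name = rep_len(order_name, n),
    year = rep_len(year, n), month = rep_len(month, n),
    lat = rep_len(lat, n), lon = rep_len(lon, n),
    basis = rep_len(basis, n), issue = rep_len(issue, n),
    stringsAsFactors = FALSE
  )
}

# Small backbone: species "<class> sp<i>" with given statuses.
mini_backbone <- function(class_name = "Aves", n_accepted = 5, n_doubtful = 2,
                          n_synonym = 3, order_name = "Ord1") {
  status <- c(rep("accepted", n_accepted), rep("doubtful", n_doubtful),
              rep("synonym", n_synonym))
  data.table::data.table(
    species = paste(class_name, "sp", seq_along(status)),
    class_name = class_name, order_name = order_name, status = status
  )
}

# Desk-scale synthetic config used by most generator-driven tests.
small_config <- function(seed = 11, n = 5000, ...) {
  synth_config(seed = seed, n_occurrences = n, ...)
}

# Two-class config with simple round numbers, for brute-force comparisons.
two_class_config <- function(seed = 5, n = 1000) {
  synth_config(
    seed = seed, n_occurrences = n,
    classes = data.frame(
      class_name = c("Alpha", "Beta"), N = c(50L, 150L),
      weight = c(0.7, 0.3), precision_rate = c(0.9, 0.6),
      o_spec = c(0.5, 0.2), o_obs = c(0.4, 0.7), o_unk = c(0.1, 0.1),
      missing_time_rate = c(0.1, 0.4), missing_space_rate = c(0.2, 0.3)
    )
  )
}
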