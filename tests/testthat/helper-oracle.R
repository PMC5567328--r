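# Independent brute-force oracles, written against plain base R data frames
# and textbook formulas, deliberately avoiding the package's own code paths
# (except eckert4_project for the shared projection definition, which has
# its own external reference oracle).

# Exhaustive per-class recomputation of every summary statistic.
oracle_summary <- function(records, backbone, level = "class",
                           cell_size = 10000, threshold = 20) {
  df <- as.data.frame(records)
  bb <- as.data.frame(backbone)
  key <- if (level == "class") "class_name" else "order_name"
  df <- df[nzchar(df[[key]]), ]
  out <- list()
  for (cl in sort(unique(df[[key]]))) {
    sub <- df[df[[key]] == cl, ]
    spp <- sub$species[nzchar(sub$species)]
    counts <- if (length(spp)) as.vector(table(spp)) else integer()
    med <- if (length(counts)) median(counts) else NA_real_
    madv <- if (length(counts)) median(abs(counts - median(counts))) else NA_real_
    bsub <- bb[bb[[key]] == cl & bb$status %in% c("accepted", "doubtful"), ]
    N <- length(unique(bsub$species))
    n20d <- 0L
    for (sp in unique(spp)) {
      rows <- sub[sub$species == sp & !is.na(sub$lat) & !is.na(sub$lon) &
                    !sub$space_issue, ]
      if (nrow(rows) == 0) next
      xy <- eckert4_project(rows$lat, rows$lon)
      cells <- unique(paste(floor(xy$x / cell_size), floor(xy$y / cell_size)))
      if (length(cells) >= threshold) n20d <- n20d + 1L
    }
    out[[cl]] <- data.frame(
      taxon = cl, nb_occ = nrow(sub), n_gt1 = length(unique(spp)),
      N = N, med_sp = med, mad = madv,
      precision = mean(sub$species_precise),
      n_gt20 = sum(table(spp) >= threshold), n_gt20d = n20d,
      p_gt1 = if (N > 0) length(unique(spp)) / N else NA_real_,
      p_gt20 = if (N > 0) sum(table(spp) >= threshold) / N else NA_real_,
      p_gt20d = if (N > 0) n20d / N else NA_real_,
      o_spec = mean(sub$origin == "Specimen"),
      o_obs = mean(sub$origin == "Observation"),
      o_unk = mean(sub$origin == "Unknown"),
      p_time = mean(sub$time_issue), p_space = mean(sub$space_issue)
    )
  }
  do.call(rbind, out)
}

# Textbook correspondence analysis of an explicitly built indicator matrix.
oracle_mca <- function(table, n_axes = 10) {
  table <- as.data.frame(table)
  Z <- NULL
  for (v in names(table)) {
    x <- droplevels(factor(table[[v]]))
    m <- matrix(0, nrow(table), nlevels(x),
                dimnames = list(NULL, paste(v, levels(x), sep = ".")))
    m[cbind(seq_len(nrow(table)), as.integer(x))] <- 1
    Z <- cbind(Z, m)
  }
  n <- nrow(Z); Q <- ncol(table); J <- ncol(Z)
  G <- Z / sum(Z)
  r <- rowSums(G); cm <- colSums(G)
  S <- diag(1 / sqrt(r)) %*% (G - r %*% t(cm)) %*% diag(1 / sqrt(cm))
  sv <- svd(S)
  k <- min(n_axes, J - Q)
  list(
    eigenvalues = sv$d[seq_len(k)]^2,
    row_coords = diag(1 / sqrt(r)) %*% sv$u[, seq_len(k)] %*% diag(sv$d[seq_len(k)]),
    col_coords = {
      cc <- diag(1 / sqrt(cm)) %*% sv$v[, seq_len(k)] %*% diag(sv$d[seq_len(k)])
      rownames(cc) <- colnames(Z); cc
    },
    J = J, Q = Q
  )
}
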