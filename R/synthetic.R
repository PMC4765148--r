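# Synthetic data generators: planted sparse-weight multi-label datasets,
# toy GO DAGs with annotation databases, and benchmark-like label
# compositions. All draws are fully determined by the seed argument.

#' Planted sparse multi-label dataset
#'
#' Generates a GO-frequency-like design (sparse non-negative integer
#' counts: zero-inflated Poisson entries, with blocks of correlated
#' columns to exercise the elastic net's grouping effect) and a planted
#' row-sparse weight matrix with exactly `k` non-zero weights per class.
#' Transformed labels follow the sign of the per-class latent score
#' \eqn{\beta_m^{*\top} x_i + b_m + \sigma \epsilon}, with the latent
#' centered per class (via its median) so both signs occur; rows left
#' without any positive label are assigned their argmax location, so every
#' label set is non-empty. Noise enters through the latent score before
#' the sign, which keeps the planted linear scorer Bayes-optimal; an
#' optional `flip_rate` adds plain label noise on top.
#'
#' @param n,t,m proteins, GO terms, locations.
#' @param k non-zero weights per class (k <= t).
#' @param magnitude_range range of the planted |weights| (default
#'   0.75--1.5, moderate effects relative to unit-count features).
#' @param sigma latent noise standard deviation (default 0.5).
#' @param corr_block_size columns per correlated block (default 5; 1
#'   disables correlation).
#' @param zero_prob probability that a count entry is structurally zero
#'   (default 0.7, mimicking sparse GO annotation).
#' @param count_lambda Poisson rate of the non-zero counts (default 1.5;
#'   counts are `1 + rpois(count_lambda)`).
#' @param flip_rate probability of flipping each transformed label.
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @return list with `x` (n x t integer matrix, columns named by synthetic
#'   GO ids), `labels` (list of label sets), `label_matrix` (-1/+1),
#'   `truth` (list: `beta` m x t planted weights, `support` per class),
#'   and the generator settings.
#' @export
make_planted_dataset <- function(n, t, m, k,
                                 magnitude_range = c(0.75, 1.5),
                                 sigma = 0.5, corr_block_size = 5L,
                                 zero_prob = 0.7, count_lambda = 1.5,
                                 flip_rate = 0, seed = 1L) {
  if (k > t) stop("k must not exceed t")
  if (n < 1L || m < 1L) stop("n and m must be >= 1")
  set.seed(seed)
  block <- max(1L, as.integer(corr_block_size))
  x <- matrix(0L, n, t)
  nblk <- ceiling(t / block)
  for (b in seq_len(nblk)) {
    cols <- ((b - 1L) * block + 1L):min(b * block, t)
    base_mask <- stats::rbinom(n, 1L, 1 - zero_prob)
    base_cnt <- stats::rpois(n, count_lambda) + 1L
    for (cc in cols) {
      share <- stats::rbinom(n, 1L, 0.7)  # share the block pattern w.p. 0.7
      mask <- ifelse(share == 1L, base_mask, stats::rbinom(n, 1L, 1 - zero_prob))
      cnt <- ifelse(share == 1L, base_cnt, stats::rpois(n, count_lambda) + 1L)
      x[, cc] <- as.integer(mask * cnt)
    }
  }
  colnames(x) <- sprintf("GO:%07d", seq_len(t))
  rownames(x) <- sprintf("SYN%04d", seq_len(n))
  beta <- matrix(0, m, t)
  for (j in seq_len(m)) {
    sup <- sample.int(t, k)
    beta[j, sup] <- stats::runif(k, magnitude_range[1L], magnitude_range[2L]) *
      sample(c(-1, 1), k, replace = TRUE)
  }
  latent <- x %*% t(beta)
  latent <- sweep(latent, 2L, apply(latent, 2L, stats::median))
  latent <- latent + sigma * matrix(stats::rnorm(n * m), n, m)
  y <- ifelse(latent > 0, 1L, -1L)
  if (flip_rate > 0) {
    flips <- matrix(stats::rbinom(n * m, 1L, flip_rate), n, m) == 1L
    y[flips] <- -y[flips]
  }
  none <- rowSums(y == 1L) == 0L
  for (i in which(none)) y[i, which.max(latent[i, ])] <- 1L
  labels <- label_matrix_to_sets(y)
  names(labels) <- rownames(x)
  list(x = x, labels = labels, label_matrix = y,
       truth = list(beta = beta,
                    support = apply(beta, 1L, function(b) which(b != 0),
                                    simplify = FALSE)),
       settings = list(n = n, t = t, m = m, k = k,
                       magnitude_range = magnitude_range, sigma = sigma,
                       corr_block_size = block, zero_prob = zero_prob,
                       count_lambda = count_lambda, flip_rate = flip_rate,
                       seed = seed))
}

#' Toy GO DAG with a matching annotation database
#'
#' Builds, for each of the three GO taxonomies, a rooted tree of the given
#' depth and branching factor, plus a controlled fraction of extra
#' child-to-parent edges between non-adjacent levels (making it a proper
#' DAG rather than a tree). An annotation database is generated alongside:
#' synthetic accessions annotated with leaf-biased term multisets.
#'
#' @param depth tree depth (>= 1; depth 1 with branching 2 gives 3 nodes
#'   per taxonomy).
#' @param branching children per node.
#' @param extra_edge_prob probability of adding a grandparent shortcut
#'   edge per eligible node (0 gives pure trees).
#' @param n_proteins accessions in the annotation database.
#' @param terms_per_protein mean number of annotation draws per accession.
#' @param seed integer seed.
#' @return list with `dag` (a `"go_dag"`) and `db` (an
#'   `"annotation_db"`).
#' @export
make_toy_dag <- function(depth, branching = 2L, extra_edge_prob = 0,
                         n_proteins = 20L, terms_per_protein = 4L,
                         seed = 1L) {
  if (depth < 1L) stop("depth must be >= 1")
  set.seed(seed)
  ids <- character(0); nss <- character(0)
  parents <- list(); etypes <- list()
  counter <- 0L
  next_id <- function() {
    counter <<- counter + 1L
    sprintf("GO:%07d", counter)
  }
  level_of <- integer(0)
  for (tax in GO_CATEGORIES) {
    root <- next_id()
    ids <- c(ids, root); nss <- c(nss, tax)
    parents[[length(parents) + 1L]] <- character(0)
    etypes[[length(etypes) + 1L]] <- character(0)
    level_of <- c(level_of, 0L)
    frontier <- root
    frontier_anc <- list(character(0))
    for (d in seq_len(depth)) {
      new_frontier <- character(0)
      new_anc <- list()
      for (fi in seq_along(frontier)) {
        p <- frontier[fi]
        anc <- c(frontier_anc[[fi]], p)
        for (b in seq_len(branching)) {
          ch <- next_id()
          ids <- c(ids, ch); nss <- c(nss, tax)
          par <- p
          et <- if (stats::runif(1) < 0.3) "part_of" else "is_a"
          ets <- et
          # occasional shortcut to a grandparent: extra DAG edge
          if (extra_edge_prob > 0 && length(anc) >= 2L &&
              stats::runif(1) < extra_edge_prob) {
            par <- c(par, anc[length(anc) - 1L])
            ets <- c(ets, "is_a")
          }
          parents[[length(parents) + 1L]] <- par
          etypes[[length(etypes) + 1L]] <- ets
          level_of <- c(level_of, d)
          new_frontier <- c(new_frontier, ch)
          new_anc[[length(new_anc) + 1L]] <- anc
        }
      }
      frontier <- new_frontier
      frontier_anc <- new_anc
    }
  }
  dag <- new_go_dag(ids, nss, ids, parents, etypes)
  # leaf-biased annotations: deeper terms are drawn more often
  wts <- (level_of + 1)^2
  lines <- character(0)
  for (p in seq_len(n_proteins)) {
    acc <- sprintf("SYNP%03d", p)
    ndraw <- max(1L, stats::rpois(1L, terms_per_protein))
    draw <- sample(seq_along(ids), ndraw, replace = TRUE, prob = wts)
    lines <- c(lines, sprintf("%s\t%s\t%s", acc, ids[draw], nss[draw]))
  }
  list(dag = dag, db = read_annotation_db(lines))
}

#' The human benchmark composition
#'
#' The printed composition of the 14-location human benchmark: per-location
#' locative protein counts and the co-location breakdown (2580 proteins
#' with one location, 480 with two, 43 with three, 3 with four; 3106
#' actual proteins, 3681 locative proteins).
#'
#' @return data.frame with columns `location`, `abbrev`, `name`,
#'   `locative`, plus attributes `colocation_breakdown` (named integer
#'   vector) and `n_actual`.
#' @export
human_benchmark_composition <- function() {
  out <- data.frame(
    location = 1:14,
    abbrev = c("CEN", "CYT", "CYK", "ER", "END", "EXT", "GOL", "LYS",
               "MIC", "MIT", "NUC", "PER", "PM", "SYN"),
    name = c("centrosome", "cytoplasm", "cytoskeleton",
             "endoplasmic reticulum", "endosome", "extracellular",
             "Golgi apparatus", "lysosome", "microsome", "mitochondrion",
             "nucleus", "peroxisome", "plasma membrane", "synapse"),
    locative = c(77L, 817L, 79L, 229L, 24L, 385L, 161L, 77L, 24L, 364L,
                 1021L, 47L, 354L, 22L))
  attr(out, "colocation_breakdown") <- c(`1` = 2580L, `2` = 480L,
                                         `3` = 43L, `4` = 3L)
  attr(out, "n_actual") <- 3106L
  out
}

#' Benchmark-like multi-label composition
#'
#' Draws a skeleton dataset of label sets over M = 14 locations whose
#' co-location-size histogram matches the human benchmark's proportions
#' at the requested scale (at `scale = 1`, exactly 2580 / 480 / 43 / 3
#' proteins with 1 / 2 / 3 / 4 locations). Location identities within
#' each set are sampled without replacement, weighted by the benchmark's
#' per-location locative counts.
#'
#' @param scale fraction of the benchmark size in (0, 1].
#' @param seed integer seed.
#' @return list with `labels` (list of label sets), `M`, `n_actual`,
#'   `n_locative`, and `breakdown` (proteins per co-location size).
#' @export
make_benchmark_like_composition <- function(scale = 1, seed = 1L) {
  if (scale <= 0 || scale > 1) stop("scale must be in (0, 1]")
  set.seed(seed)
  comp <- human_benchmark_composition()
  breakdown <- round(attr(comp, "colocation_breakdown") * scale)
  breakdown[1L] <- max(breakdown[1L], 1L)
  wts <- comp$locative
  labels <- list()
  for (k in seq_along(breakdown)) {
    nk <- breakdown[k]
    if (nk == 0L) next
    for (i in seq_len(nk)) {
      labels[[length(labels) + 1L]] <- sort(sample(comp$location, k,
                                                   prob = wts))
    }
  }
  names(labels) <- sprintf("BMK%04d", seq_along(labels))
  list(labels = labels, M = 14L, n_actual = length(labels),
       n_locative = sum(lengths(labels)),
       breakdown = as.integer(breakdown))
}
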