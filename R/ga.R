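#' Genetic-algorithm configuration
#'
#' Parameters of the segment-encoded GA: each individual is a set of
#' `k_segments` unique spectral-segment ids, fitness is LOOCV-LDA accuracy on
#' the selected variables, and the search is repeated `n_runs` times for
#' consensus band counting.
#'
#' @param population_size Individuals per generation.
#' @param generations Generations per run.
#' @param crossover_prob Probability that a mated pair undergoes single-point
#'   crossover.
#' @param mutation_prob Per-individual probability of mutating one randomly
#'   chosen position per generation.
#' @param copy_fraction Fraction of top individuals copied over the same
#'   number of worst individuals when forming the mating pool.
#' @param k_segments Segments per chromosome.
#' @param n_runs Independent GA repetitions for consensus counting.
#' @param ridge Relative ridge passed to the LDA fitness (see [fit_lda()]).
#' @param balanced Use the mean of per-class accuracies instead of overall
#'   accuracy as the fitness.
#' @param seed Master seed; each of the `n_runs` repetitions draws its own
#'   substream.
#' @return A validated `ga_config` list.
#' @export
ga_config <- function(population_size = 20, generations = 100,
                      crossover_prob = 0.70, mutation_prob = 0.05,
                      copy_fraction = 0.25, k_segments = 6, n_runs = 100,
                      ridge = 1e-8, balanced = FALSE, seed = 1) {
  cfg <- list(population_size = as.integer(population_size),
              generations = as.integer(generations),
              crossover_prob = crossover_prob, mutation_prob = mutation_prob,
              copy_fraction = copy_fraction, k_segments = as.integer(k_segments),
              n_runs = as.integer(n_runs), ridge = ridge,
              balanced = isTRUE(balanced), seed = seed)
  if (cfg$population_size < 2) stop("population_size must be >= 2", call. = FALSE)
  if (cfg$generations < 0) stop("generations must be >= 0", call. = FALSE)
  for (p in c("crossover_prob", "mutation_prob", "copy_fraction")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(sprintf("%s must be in [0,1]", p), call. = FALSE)
  }
  if (ceiling(cfg$copy_fraction * cfg$population_size) < 1) {
    stop("copy_fraction * population_size must round up to >= 1", call. = FALSE)
  }
  if (cfg$k_segments < 1) stop("k_segments must be >= 1", call. = FALSE)
  if (cfg$n_runs < 1) stop("n_runs must be >= 1", call. = FALSE)
  class(cfg) <- "ga_config"
  cfg
}

# sample() without the length-1 surprise
resample <- function(x, n) x[sample.int(length(x), n)]

#' Random initial GA population
#'
#' Each chromosome is `k_segments` unique segment ids drawn uniformly without
#' replacement; stored in canonical (ascending) order.
#'
#' @param ga A [ga_config()].
#' @param n_seg Number of available segments.
#' @return List of integer vectors.
#' @export
init_population <- function(ga, n_seg) {
  if (ga$k_segments > n_seg) {
    stop(sprintf("k_segments (%d) exceeds number of segments (%d)",
                 ga$k_segments, n_seg), call. = FALSE)
  }
  lapply(seq_len(ga$population_size),
         function(i) sort(resample(seq_len(n_seg), ga$k_segments)))
}

check_chromosome <- function(chrom, k, n_seg) {
  is.numeric(chrom) && length(chrom) == k && !anyDuplicated(chrom) &&
    all(chrom >= 1) && all(chrom <= n_seg) && !is.unsorted(chrom)
}

# best-to-worst ordering: fitness descending, ties by ascending lexicographic
# chromosome order (reproducibility contract)
rank_population <- function(population, fitnesses) {
  genes <- as.data.frame(do.call(rbind, population))
  do.call(order, c(list(-fitnesses), genes))
}

#' Form the mating pool by elitist copy
#'
#' The top `ceiling(copy_fraction * N)` chromosomes overwrite the same number
#' of worst chromosomes; pool size is unchanged.
#'
#' @param population List of chromosomes.
#' @param fitnesses Numeric vector of their fitness values.
#' @param ga A [ga_config()].
#' @return List of chromosomes (the mating pool).
#' @export
select_copy <- function(population, fitnesses, ga) {
  n <- length(population)
  stopifnot(length(fitnesses) == n)
  n_copy <- as.integer(ceiling(ga$copy_fraction * n))
  ord <- rank_population(population, fitnesses)
  pool <- population
  best <- ord[seq_len(n_copy)]
  worst <- ord[seq.int(n - n_copy + 1L, n)]
  pool[worst] <- population[best]
  pool
}

#' Single-point crossover of two chromosomes
#'
#' With both parents in canonical ascending order, a cut site is drawn
#' uniformly from `1..k-1` and the tails are swapped. Duplicate ids created
#' in a child are repaired by redrawing uniformly from the segments it does
#' not yet contain.
#'
#' @param a,b Parent chromosomes (unique sorted segment ids of equal length).
#' @param n_seg Number of available segments.
#' @param cut Optional fixed cut site (for testing); drawn uniformly when
#'   `NULL`.
#' @return List of two child chromosomes.
#' @export
crossover <- function(a, b, n_seg, cut = NULL) {
  k <- length(a)
  stopifnot(length(b) == k, k >= 2)
  a <- sort(as.integer(a)); b <- sort(as.integer(b))
  if (is.null(cut)) cut <- resample(seq_len(k - 1L), 1)
  repair <- function(child) {
    dup <- duplicated(child)
    if (any(dup)) {
      unused <- setdiff(seq_len(n_seg), child)
      child[dup] <- resample(unused, sum(dup))
    }
    sort(child)
  }
  c1 <- repair(c(a[seq_len(cut)], b[seq.int(cut + 1L, k)]))
  c2 <- repair(c(b[seq_len(cut)], a[seq.int(cut + 1L, k)]))
  list(c1, c2)
}

#' Mutate a chromosome
#'
#' With probability `mutation_prob`, one uniformly chosen position is
#' replaced by a uniformly chosen segment id not already present; otherwise
#' the chromosome is returned unchanged (also when no unused id exists).
#'
#' @param chrom Chromosome (unique sorted segment ids).
#' @param ga A [ga_config()].
#' @param n_seg Number of available segments.
#' @return Possibly mutated chromosome in canonical order.
#' @export
mutate <- function(chrom, ga, n_seg) {
  if (stats::runif(1) >= ga$mutation_prob) return(chrom)
  unused <- setdiff(seq_len(n_seg), chrom)
  if (!length(unused)) return(chrom)
  pos <- resample(seq_along(chrom), 1)
  chrom[pos] <- resample(unused, 1)
  sort(chrom)
}

#' Memoized LOOCV-LDA fitness function
#'
#' Returns a closure mapping a chromosome to its LOOCV-LDA classification
#' accuracy on the expanded variable subset. Evaluations are cached by
#' chromosome (canonical order), so repeated chromosomes — ubiquitous late in
#' a GA run — cost one lookup; cached and fresh values are identical because
#' the evaluation is deterministic.
#'
#' @param data Labelled, preprocessed [spectra_set()].
#' @param idx A [build_segment_index()] over the data's grid.
#' @param ridge Relative ridge for the LDA.
#' @param balanced Use mean per-class accuracy instead of overall accuracy.
#' @return Function `(chromosome) -> accuracy in [0, 1]`, with attribute
#'   `cache` (environment; `length(cache)` counts unique evaluations).
#' @export
make_fitness <- function(data, idx, ridge = 1e-8, balanced = FALSE) {
  check_two_classes(data, min_per_class = 3)
  cache <- new.env(parent = emptyenv())
  f <- function(chrom) {
    key <- paste(chrom, collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    vars <- expand_chromosome(chrom, idx)
    cv <- loocv(data, variables = vars, ridge = ridge)
    acc <- if (balanced) {
      mean(c(mean(cv$predicted[cv$label == "cancer"] == "cancer"),
             mean(cv$predicted[cv$label == "normal"] == "normal")))
    } else {
      mean(cv$predicted == cv$label)
    }
    cache[[key]] <- acc
    acc
  }
  attr(f, "cache") <- cache
  f
}

#' One genetic-algorithm run
#'
#' Generation loop: evaluate fitness; elitism (if the all-time best
#' chromosome is absent and no current individual matches its fitness, it
#' replaces the worst individual); form the mating pool by elitist copy;
#' pair pool members randomly and cross each pair with probability
#' `crossover_prob`; mutate each individual. The recorded best-fitness
#' history is non-decreasing by construction.
#'
#' @param data Labelled, preprocessed [spectra_set()].
#' @param ga A [ga_config()].
#' @param idx A [build_segment_index()] over the data's grid.
#' @param seed RNG seed for this run (defaults to `ga$seed`).
#' @param fitness Optional fitness closure from [make_fitness()] (shared
#'   across runs to pool the memoization cache).
#' @return A `ga_run` list: `best_chromosome`, `best_fitness`, `history`
#'   (data frame `generation`, `best`, `mean` — generation 0 is the initial
#'   population), `n_unique_evaluations`.
#' @export
run_ga <- function(data, ga, idx, seed = ga$seed, fitness = NULL) {
  n_seg <- n_segments(idx)
  if (is.null(fitness)) fitness <- make_fitness(data, idx, ridge = ga$ridge,
                                                balanced = ga$balanced)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)

  pop <- init_population(ga, n_seg)
  best_chrom <- NULL
  best_fit <- -Inf
  hist_best <- hist_mean <- numeric(ga$generations + 1L)

  evaluate <- function(pop) vapply(pop, fitness, numeric(1))

  fits <- evaluate(pop)
  for (g in 0:ga$generations) {
    if (g > 0) {
      pool <- select_copy(pop, fits, ga)
      ord <- resample(seq_along(pool), length(pool))
      newpop <- pool
      i <- 1L
      while (i + 1L <= length(pool)) {
        pa <- pool[[ord[i]]]; pb <- pool[[ord[i + 1L]]]
        if (stats::runif(1) < ga$crossover_prob) {
          kids <- crossover(pa, pb, n_seg)
          newpop[[ord[i]]] <- kids[[1]]; newpop[[ord[i + 1L]]] <- kids[[2]]
        } else {
          newpop[[ord[i]]] <- pa; newpop[[ord[i + 1L]]] <- pb
        }
        i <- i + 2L
      }
      pop <- lapply(newpop, mutate, ga = ga, n_seg = n_seg)
      fits <- evaluate(pop)
      if (max(fits) < best_fit) {  # elitism reinsertion
        worst <- rank_population(pop, fits)[length(pop)]
        pop[[worst]] <- best_chrom
        fits[worst] <- best_fit
      }
    }
    top <- rank_population(pop, fits)[1]
    if (fits[top] > best_fit ||
        (fits[top] == best_fit && is.null(best_chrom))) {
      best_fit <- fits[top]
      best_chrom <- pop[[top]]
    }
    hist_best[g + 1L] <- best_fit
    hist_mean[g + 1L] <- mean(fits)
  }
  structure(list(best_chromosome = best_chrom, best_fitness = best_fit,
                 history = data.frame(generation = 0:ga$generations,
                                      best = hist_best, mean = hist_mean),
                 n_unique_evaluations = length(attr(fitness, "cache"))),
            class = "ga_run")
}

#' @export
print.ga_run <- function(x, ...) {
  cat(sprintf("<ga_run> best fitness %.4f, segments {%s}, %d generations\n",
              x$best_fitness, paste(x$best_chromosome, collapse = ", "),
              max(x$history$generation)))
  invisible(x)
}

#' Consensus band counting over repeated GA runs
#'
#' Runs the GA `n_runs` times from independent RNG substreams of the master
#' seed and cumulatively counts the segments of each run's best chromosome.
#' The fitness cache is shared across runs (caching never changes values —
#' the fitness is deterministic).
#'
#' @inheritParams run_ga
#' @param n_runs Number of independent runs (defaults to `ga$n_runs`).
#' @param verbose Print one line per run.
#' @return A `band_counts` list: `counts` (integer per segment, summing to
#'   `n_runs * k_segments`), `n_runs`, `k_segments`, `runs` (per-run best
#'   fitness and chromosome).
#' @export
consensus_counts <- function(data, ga, idx, n_runs = ga$n_runs,
                             seed = ga$seed, verbose = FALSE) {
  n_seg <- n_segments(idx)
  fitness <- make_fitness(data, idx, ridge = ga$ridge, balanced = ga$balanced)
  counts <- integer(n_seg)
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    res <- run_ga(data, ga, idx, seed = substream_seed(seed, r), fitness = fitness)
    counts[res$best_chromosome] <- counts[res$best_chromosome] + 1L
    runs[[r]] <- data.frame(run = r, best_fitness = res$best_fitness,
                            best_chromosome = paste(res$best_chromosome, collapse = ","))
    if (verbose) {
      message(sprintf("run %d/%d: fitness %.4f, segments {%s}", r, n_runs,
                      res$best_fitness, runs[[r]]$best_chromosome))
    }
  }
  structure(list(counts = counts, n_runs = n_runs, k_segments = ga$k_segments,
                 runs = do.call(rbind, runs)),
            class = "band_counts")
}

#' @export
print.band_counts <- function(x, ...) {
  nz <- which(x$counts > 0)
  top <- nz[order(-x$counts[nz], nz)][seq_len(min(10, length(nz)))]
  cat(sprintf("<band_counts> %d runs x %d segments (sum %d)\n",
              x$n_runs, x$k_segments, sum(x$counts)))
  cat("  top segments:", paste(sprintf("%d(%d)", top, x$counts[top]), collapse = " "), "\n")
  invisible(x)
}

#' Extract the top consensus bands
#'
#' Segments are ranked by cumulative count (descending, ties broken by lower
#' segment id) and taken greedily; adjacent selected segments merge into one
#' contiguous band; selection stops as soon as `k` bands exist.
#'
#' @param counts A `band_counts` from [consensus_counts()] (or a bare integer
#'   vector of per-segment counts).
#' @param idx The [build_segment_index()] the counts refer to.
#' @param k Number of bands to report.
#' @return Data frame with one row per band: `band`, `seg_lo`, `seg_hi`,
#'   `n_segments`, `count` (summed over member segments) and, when the index
#'   carries a grid, `wn_lo`, `wn_hi` (cm^-1).
#' @export
top_bands <- function(counts, idx, k = 6) {
  cnt <- if (inherits(counts, "band_counts")) counts$counts else as.integer(counts)
  if (length(cnt) != n_segments(idx)) {
    stop("counts length does not match the segment index", call. = FALSE)
  }
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  nz <- which(cnt > 0)
  ord <- nz[order(-cnt[nz], nz)]
  selected <- integer(0)
  n_bands <- 0L
  for (s in ord) {
    selected <- sort(c(selected, s))
    n_bands <- sum(diff(selected) > 1) + 1L
    if (n_bands == k) break
  }
  if (n_bands != k) {
    stop(sprintf("only %d band(s) can be formed from %d nonzero-count segments; need %d",
                 n_bands, length(nz), k), call. = FALSE)
  }
  brk <- c(0, which(diff(selected) > 1), length(selected))
  bands <- lapply(seq_len(length(brk) - 1), function(j) {
    segs <- selected[(brk[j] + 1):brk[j + 1]]
    row <- data.frame(band = j, seg_lo = min(segs), seg_hi = max(segs),
                      n_segments = length(segs), count = sum(cnt[segs]))
    if (!is.null(idx$wn_lo)) {
      row$wn_lo <- idx$wn_lo[min(segs)]
      row$wn_hi <- idx$wn_hi[max(segs)]
    }
    row
  })
  do.call(rbind, bands)
}
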