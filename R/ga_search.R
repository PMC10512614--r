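## Genetic-algorithm refinement of the filter-count chromosome under the
## accuracy-plus-parameter-budget objective, with single-elite selection.

#' GA configuration
#'
#' @param generations number of generations (default 10).
#' @param pop_size individuals per generation (default 10).
#' @param elite_count individuals copied unchanged into the next
#'   generation (default 1; must stay below `pop_size`).
#' @param bounds inclusive filter-count bounds (even grid), default
#'   `c(2, 128)`.
#' @param mutation_rate per-gene mutation probability.
#' @param crossover_rate probability an offspring is produced by uniform
#'   crossover rather than copied from a single parent.
#' @param seed integer seed.
#' @return object of class `ga_config`.
#' @export
ga_config <- function(generations = 10L, pop_size = 10L, elite_count = 1L,
                      bounds = c(2L, 128L), mutation_rate = 0.2,
                      crossover_rate = 0.9, seed = 0L) {
  if (elite_count >= pop_size)
    stop("elite_count must be smaller than pop_size")
  if (bounds[1] > bounds[2]) stop("bounds must satisfy low <= high")
  for (r in c(mutation_rate, crossover_rate))
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]")
  structure(list(generations = as.integer(generations),
                 pop_size = as.integer(pop_size),
                 elite_count = as.integer(elite_count),
                 bounds = as.integer(bounds),
                 mutation_rate = mutation_rate, crossover_rate = crossover_rate,
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' GA objective: accuracy shortfall plus filter budget
#'
#' `OF = 1 - acc + sum(F_k) / F_max` where `F_max` is the largest filter
#' sum the structure admits (768 for 6 genes bounded by 128).
#'
#' @param acc mean validation accuracy in `[0, 1]`.
#' @param chrom a [chromosome()].
#' @param f_max maximum total filter count (default `128 * 6`).
#' @return objective value (smaller is better), in `[12/768, 2]` for
#'   legal chromosomes.
#' @export
objective <- function(acc, chrom, f_max = 128 * 6) {
  if (!is.numeric(acc) || length(acc) != 1 || is.na(acc) || acc < 0 || acc > 1)
    stop("acc must be a single value in [0, 1]")
  chrom <- chromosome(chrom)
  1 - acc + sum(chrom) / f_max
}

## Round to the even grid and clip into bounds.
clip_even <- function(x, bounds) {
  x <- 2L * as.integer(round(x / 2))
  pmin(bounds[2], pmax(bounds[1], x))
}

#' Mutate a chromosome
#'
#' Each gene is perturbed independently with probability
#' `cfg$mutation_rate` by `+/- 2k` (k in 1..3, smaller steps more
#' likely), clipped to the even grid within bounds.
#'
#' @param chrom a [chromosome()].
#' @param cfg a [ga_config()].
#' @param seed integer seed.
#' @return mutated [chromosome()].
#' @export
mutate <- function(chrom, cfg, seed = 0L) {
  g <- as.integer(chromosome(chrom))
  with_seed(seed, {
    hit <- stats::runif(6) < cfg$mutation_rate
    if (any(hit)) {
      k <- sample(1:3, sum(hit), replace = TRUE, prob = c(0.6, 0.3, 0.1))
      sgn <- sample(c(-1L, 1L), sum(hit), replace = TRUE)
      g[hit] <- g[hit] + 2L * k * sgn
    }
    chromosome(clip_even(g, cfg$bounds))
  })
}

#' Uniform per-gene crossover
#'
#' @param a,b parent [chromosome()]s.
#' @param cfg a [ga_config()].
#' @param seed integer seed.
#' @return offspring [chromosome()].
#' @export
crossover <- function(a, b, cfg, seed = 0L) {
  a <- as.integer(chromosome(a)); b <- as.integer(chromosome(b))
  with_seed(seed, {
    pick <- stats::runif(6) < 0.5
    chromosome(ifelse(pick, a, b))
  })
}

#' Evolve a chromosome population against an accuracy evaluator
#'
#' Tournament selection (size 2) on the objective, uniform crossover,
#' per-gene mutation, and single-elite promotion: the best individual is
#' copied unchanged into the next generation with its recorded score, so
#' the generation-best objective is non-increasing even under noisy
#' evaluators. Evaluations are cached per chromosome.
#'
#' @param evaluator function `chromosome -> mean accuracy in [0, 1]`.
#' @param cfg a [ga_config()].
#' @param f_max maximum total filter count for the objective.
#' @return list of class `ga_result`: `best` (list with `chromosome`,
#'   `acc`, `of`) and `history` (data.frame per generation: `generation`,
#'   `best_of`, `best_acc`, `sum_filters`, `mean_sum_filters`,
#'   `chromosome`).
#' @export
evolve <- function(evaluator, cfg = ga_config(), f_max = 128 * 6) {
  stopifnot(inherits(cfg, "ga_config"))
  score_cache <- new.env(parent = emptyenv())
  eval_chrom <- function(ch) {
    key <- paste(as.integer(ch), collapse = "_")
    if (!is.null(score_cache[[key]])) return(score_cache[[key]])
    acc <- evaluator(ch)
    if (!is.numeric(acc) || is.na(acc))
      stop("evaluator failed on chromosome [", key, "]")
    rec <- list(chromosome = ch, acc = acc, of = objective(acc, ch, f_max))
    score_cache[[key]] <- rec
    rec
  }
  rng_stream <- function(i) derive_seed(cfg$seed, i)
  pop <- with_seed(rng_stream(0L), {
    lapply(seq_len(cfg$pop_size), function(i)
      chromosome(clip_even(stats::runif(6, cfg$bounds[1], cfg$bounds[2]), cfg$bounds)))
  })
  history <- list()
  best <- NULL
  ctr <- 0L
  for (gen in seq_len(cfg$generations)) {
    scored <- lapply(pop, eval_chrom)
    ofs <- vapply(scored, `[[`, numeric(1), "of")
    ord <- order(ofs)
    gen_best <- scored[[ord[1]]]
    if (is.null(best) || gen_best$of < best$of) best <- gen_best
    history[[gen]] <- data.frame(
      generation = gen, best_of = best$of, best_acc = best$acc,
      sum_filters = sum(best$chromosome),
      mean_sum_filters = mean(vapply(pop, sum, numeric(1))),
      chromosome = paste(as.integer(best$chromosome), collapse = "-"))
    if (gen == cfg$generations) break
    elite <- lapply(scored[ord[seq_len(cfg$elite_count)]], `[[`, "chromosome")
    offspring <- list()
    while (length(offspring) < cfg$pop_size - cfg$elite_count) {
      ctr <- ctr + 1L
      child <- with_seed(rng_stream(1000L + ctr), {
        tourney <- function() {
          i <- sample.int(cfg$pop_size, 2)
          if (ofs[i[1]] <= ofs[i[2]]) pop[[i[1]]] else pop[[i[2]]]
        }
        p1 <- tourney(); p2 <- tourney()
        ch <- if (stats::runif(1) < cfg$crossover_rate)
          chromosome(ifelse(stats::runif(6) < 0.5, as.integer(p1), as.integer(p2)))
        else p1
        hit <- stats::runif(6) < cfg$mutation_rate
        g <- as.integer(ch)
        if (any(hit)) {
          k <- sample(1:3, sum(hit), replace = TRUE, prob = c(0.6, 0.3, 0.1))
          sgn <- sample(c(-1L, 1L), sum(hit), replace = TRUE)
          g[hit] <- g[hit] + 2L * k * sgn
        }
        chromosome(clip_even(g, cfg$bounds))
      })
      offspring[[length(offspring) + 1L]] <- child
    }
    pop <- c(elite, offspring)
  }
  structure(list(best = best, history = do.call(rbind, history), cfg = cfg),
            class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat("<ga_result> best OF =", format(x$best$of, digits = 6),
      " acc =", format(x$best$acc, digits = 4),
      " chromosome = [", paste(as.integer(x$best$chromosome), collapse = ", "), "]\n")
  invisible(x)
}
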