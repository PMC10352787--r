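# Genetic-algorithm inference of the S_ij coupling efficiencies.

#' Genetic algorithm configuration
#'
#' Defaults follow the recommended settings for S_ij inference: population
#' size 60 held constant across an analysis and 100 generations, by which
#' point the best solution has plateaued.  The operator suite is standard
#' real-valued GA practice: tournament selection (k = 2), uniform crossover,
#' Gaussian mutation clipped to [0, 1], and single-individual elitism.
#'
#' @param population_size Number of chromosomes per generation (>= 4).
#' @param generations Number of generations (>= 1).
#' @param crossover_prob Probability a parent pair undergoes uniform
#'   crossover.
#' @param mutation_prob Per-weight mutation probability.
#' @param mutation_sd Gaussian mutation step standard deviation.
#' @param tournament_size Tournament size for selection.
#' @param elite Number of best individuals copied unchanged (>= 1 keeps the
#'   fitness history non-decreasing).
#' @param seed Integer seed for reproducible runs.
#' @return A `ga_config` list.
#' @export
ga_config <- function(population_size = 60, generations = 100,
                      crossover_prob = 0.8, mutation_prob = 0.1,
                      mutation_sd = 0.1, tournament_size = 2, elite = 1,
                      seed = NULL) {
  stopifnot(population_size >= 4, generations >= 1,
            crossover_prob >= 0, crossover_prob <= 1,
            mutation_prob >= 0, mutation_prob <= 1,
            mutation_sd > 0, tournament_size >= 1, elite >= 0)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob, mutation_sd = mutation_sd,
                 tournament_size = as.integer(tournament_size),
                 elite = as.integer(elite), seed = seed),
            class = "ga_config")
}

# Precompute everything the fitness needs: the codons entering the
# correlation (sense codons of multi-codon families with defined RSCU), the
# fixed RSCU ranks, and the codon x class contribution matrix.
fitness_context <- function(tgcn, ref_rscu, rules, partition = NULL) {
  partition <- partition %||%
    build_family_partition(attr(rules, "genetic_code_id"))
  multi <- unlist(lapply(partition$families,
                         function(f) if (f$m >= 2) f$codons else NULL))
  codons <- intersect(rownames(adaptiveness_matrix(tgcn, rules)), multi)
  codons <- codons[!is.na(ref_rscu[codons])]
  if (length(codons) < 3)
    stop("fewer than 3 codons with defined RSCU and adaptiveness")
  C <- adaptiveness_matrix(tgcn, rules)[codons, , drop = FALSE]
  list(C = C, rscu_rank = rank(ref_rscu[codons]), codons = codons)
}

fitness_eval <- function(ctx, s_full) {
  W <- as.vector(ctx$C %*% (1 - s_full))
  if (stats::sd(W) == 0) stop("zero variance in W across codons")
  stats::cor(ctx$rscu_rank, rank(W))
}

#' GA fitness: Spearman correlation between reference RSCU and W_i
#'
#' The objective the genetic algorithm maximizes: the Spearman rank
#' correlation, at the level of codons, between the pooled RSCU of the
#' reference set and the absolute adaptiveness \eqn{W_i} implied by a
#' candidate S_ij vector.  The correlation runs over sense codons of
#' multi-codon families whose RSCU is defined; ties get average ranks.
#'
#' @param s An [sij_weights()] vector (or partial named vector).
#' @param tgcn A [tgcn_table()].
#' @param ref_rscu Reference RSCU from [reference_rscu()].
#' @param rules A [wobble_rules()] table.
#' @param partition Optional [build_family_partition()].
#' @return Spearman rho in [-1, 1].
#' @export
sij_fitness <- function(s, tgcn, ref_rscu, rules, partition = NULL) {
  ctx <- fitness_context(tgcn, ref_rscu, rules, partition)
  fitness_eval(ctx, sij_weights(s))
}

default_free_classes <- function(prokaryote) {
  if (prokaryote) c("GU", "IC", "IA", "UG", "LA") else c("GU", "IC", "IA", "UG")
}

#' Infer S_ij weights by genetic algorithm
#'
#' Evolves a population of candidate S_ij vectors (chromosomes of the free
#' wobble-class weights, Watson-Crick classes pinned at 0) to maximize
#' [sij_fitness()].  Initial weights are uniform on [0, 1]; each generation
#' applies tournament selection, uniform crossover, Gaussian mutation clipped
#' to [0, 1], and elitism.  With a fixed seed the run is bit-reproducible,
#' and elitism makes the per-generation best-fitness history non-decreasing.
#'
#' @param config A [ga_config()].
#' @param tgcn A [tgcn_table()].
#' @param ref_rscu Reference RSCU from [reference_rscu()].
#' @param rules A [wobble_rules()] table.
#' @param prokaryote Include the lysidine L:A class as a free parameter
#'   (default taken from `rules`).
#' @param free_classes Interaction classes to optimize (default: wobble
#'   classes, plus L:A in prokaryote mode).
#' @param pinned An [sij_weights()] vector supplying the fixed values of the
#'   non-free classes (default all 0).
#' @param partition Optional [build_family_partition()].
#' @return A `ga_result`: `best_s` (full [sij_weights()] vector),
#'   `best_fitness`, per-generation best `history`, `evaluations`, the config
#'   and the free class names.
#' @export
run_ga <- function(config = ga_config(), tgcn, ref_rscu, rules,
                   prokaryote = isTRUE(attr(rules, "prokaryote")),
                   free_classes = default_free_classes(prokaryote),
                   pinned = sij_weights(), partition = NULL) {
  ctx <- fitness_context(tgcn, ref_rscu, rules, partition)
  if (!is.null(config$seed)) set.seed(config$seed)
  np <- config$population_size
  nf <- length(free_classes)
  s_full <- sij_weights(pinned)

  eval_pop <- function(pop) {
    apply(pop, 1, function(g) {
      s <- s_full
      s[free_classes] <- g
      tryCatch(fitness_eval(ctx, s), error = function(e) NA_real_)
    })
  }

  pop <- matrix(stats::runif(np * nf), np, nf)
  fit <- eval_pop(pop)
  evaluations <- np
  if (all(is.na(fit))) stop("fitness undefined for the entire initial population")
  fit[is.na(fit)] <- -Inf

  best_i <- which.max(fit)
  best_gene <- pop[best_i, ]
  best_fit <- fit[best_i]
  history <- numeric(config$generations)

  for (gen in seq_len(config$generations)) {
    # tournament selection of 2 parents per offspring
    pick <- function() {
      cand <- sample.int(np, config$tournament_size, replace = TRUE)
      cand[which.max(fit[cand])]
    }
    n_off <- np - config$elite
    offspring <- matrix(0, n_off, nf)
    i <- 1L
    while (i <= n_off) {
      p1 <- pop[pick(), ]
      p2 <- pop[pick(), ]
      if (stats::runif(1) < config$crossover_prob) {
        mask <- stats::runif(nf) < 0.5
        c1 <- ifelse(mask, p1, p2)
        c2 <- ifelse(mask, p2, p1)
      } else {
        c1 <- p1; c2 <- p2
      }
      offspring[i, ] <- c1
      if (i + 1L <= n_off) offspring[i + 1L, ] <- c2
      i <- i + 2L
    }
    # Gaussian mutation, clipped to [0, 1]
    mut <- matrix(stats::runif(n_off * nf) < config$mutation_prob, n_off, nf)
    step <- matrix(stats::rnorm(n_off * nf, 0, config$mutation_sd), n_off, nf)
    offspring <- pmin(pmax(offspring + mut * step, 0), 1)

    elite_idx <- utils::head(order(fit, decreasing = TRUE), config$elite)
    new_pop <- rbind(pop[elite_idx, , drop = FALSE], offspring)
    new_fit <- c(fit[elite_idx], eval_pop(offspring))
    evaluations <- evaluations + n_off
    new_fit[is.na(new_fit)] <- -Inf
    pop <- new_pop
    fit <- new_fit

    gi <- which.max(fit)
    if (fit[gi] > best_fit) {
      best_fit <- fit[gi]
      best_gene <- pop[gi, ]
    }
    history[gen] <- best_fit
  }

  best_s <- s_full
  best_s[free_classes] <- best_gene
  structure(list(best_s = best_s, best_fitness = best_fit, history = history,
                 evaluations = evaluations, free_classes = free_classes,
                 config = config, seed = config$seed),
            class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat("ga_result: best fitness", format(x$best_fitness, digits = 4), "after",
      length(x$history), "generations (", x$evaluations, "evaluations )\n")
  free <- x$best_s[x$free_classes]
  cat("  best S_ij:", paste(names(free), format(free, digits = 3),
                            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Exhaustive grid-search oracle for small S_ij instances
#'
#' Evaluates [sij_fitness()] on a full lattice over at most 3 free classes,
#' returning the argmax.  Serves as an independent check that the GA reaches
#' the global optimum on low-dimensional instances.
#'
#' @param tgcn A [tgcn_table()].
#' @param ref_rscu Reference RSCU vector.
#' @param rules A [wobble_rules()] table.
#' @param free_classes Up to 3 interaction classes to scan.
#' @param grid_step Lattice spacing in [0, 1] (default 0.01).
#' @param pinned Fixed values for the remaining classes.
#' @param partition Optional [build_family_partition()].
#' @return List with `best_s`, `best_fitness` and `evaluations`.
#' @export
grid_search_oracle <- function(tgcn, ref_rscu, rules, free_classes,
                               grid_step = 0.01, pinned = sij_weights(),
                               partition = NULL) {
  if (length(free_classes) > 3)
    stop("grid search limited to <= 3 free classes")
  ctx <- fitness_context(tgcn, ref_rscu, rules, partition)
  s_full <- sij_weights(pinned)
  axis <- seq(0, 1, by = grid_step)
  grid <- as.matrix(expand.grid(rep(list(axis), length(free_classes))))
  best_fit <- -Inf
  best_row <- grid[1, ]
  for (i in seq_len(nrow(grid))) {
    s <- s_full
    s[free_classes] <- grid[i, ]
    f <- tryCatch(fitness_eval(ctx, s), error = function(e) NA_real_)
    if (!is.na(f) && f > best_fit) {
      best_fit <- f
      best_row <- grid[i, ]
    }
  }
  best_s <- s_full
  best_s[free_classes] <- best_row
  list(best_s = best_s, best_fitness = best_fit, evaluations = nrow(grid))
}
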