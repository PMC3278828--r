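# Hybrid evolutionary algorithm: genetic programming evolves single
# IF-THEN-ELSE rule sets over the typed grammar in hea_rules.R (boolean
# condition, two arithmetic branches); a genetic algorithm then refines the
# numeric constants of the best rule, using non-convex linear-combination
# crossover of multiple parents. Independent repetitions are compared by
# test-set RMSE and an optional GA bit-mask selects the variable subset
# exposed to the GP terminals.

#' Evolutionary search configuration
#'
#' @param population GP population size (default 500; a scaled-down test
#'   profile uses 100).
#' @param generations GP generations (default 100; scaled profile 50).
#' @param tournament_size Tournament selection size.
#' @param p_crossover,p_mutation Subtree crossover / mutation probabilities.
#' @param max_depth Maximum tree depth of evolved expressions.
#' @param const_range Range of ephemeral numeric constants.
#' @param use_exp Include `exp` in the arithmetic function set.
#' @param ga_population,ga_generations GA settings for constant refinement.
#' @param ga_parents Parent count m of the linear-combination crossover.
#' @param ga_coef_range Range the combination coefficients are drawn from
#'   before normalization to sum 1; the default \[-0.5, 1.5\] makes the
#'   combination non-convex (coefficients may leave \[0, 1\]).
#' @param tune_elite Apply a small-budget GA constant optimization to the
#'   best individual every generation (the hybrid's defining step: GP
#'   proposes structures, the GA fits their parameters).
#' @param p_tune Probability that a freshly created offspring receives the
#'   same small-budget constant optimization, so promising structures with
#'   poorly set constants are not lost to selection.
#' @param tune_population,tune_generations Budget of the in-loop GA tuner.
#' @param runs Independent repetitions (100 in the full study profile).
#' @param select_variables Evolve a GA bit-mask over the candidate variables
#'   before each run's GP (fitness: best rule's validation RMSE, falling
#'   back to training RMSE without a validation set).
#' @param mask_population,mask_generations Budget of the bit-mask GA.
#' @param seed Master seed; per-run seeds are derived from it.
#' @return An `hea_config` list.
#' @export
hea_config <- function(population = 500, generations = 100,
                       tournament_size = 4, p_crossover = 0.9,
                       p_mutation = 0.1, max_depth = 6,
                       const_range = c(-100, 100), use_exp = FALSE,
                       ga_population = 50, ga_generations = 50,
                       ga_parents = 3, ga_coef_range = c(-0.5, 1.5),
                       tune_elite = TRUE, p_tune = 0.1,
                       tune_population = 12, tune_generations = 8,
                       runs = 100, select_variables = FALSE,
                       mask_population = 8, mask_generations = 3,
                       seed = 1L) {
  stopifnot(population >= 2, generations >= 1, tournament_size >= 1,
            p_crossover >= 0, p_crossover <= 1, p_mutation >= 0,
            p_mutation <= 1, max_depth >= 2, ga_parents >= 2, runs >= 1)
  structure(as.list(environment()), class = "hea_config")
}

#' Scaled-down evolutionary profile
#'
#' Reduced search budget (population 100, 50 generations, 5 runs) for
#' desk-scale experiments and tests.
#'
#' @param ... Overrides passed to [hea_config()].
#' @return An `hea_config`.
#' @export
hea_config_scaled <- function(...) {
  hea_config(population = 100, generations = 50, runs = 5, ...)
}

# ---- random typed trees ---------------------------------------------------

arith_ops <- function(config) {
  c(ARITH_BINARY, "lnabs", if (config$use_exp) "exp")
}

random_leaf <- function(variables, config) {
  if (stats::runif(1) < 0.5) {
    expr_var(sample(variables, 1))
  } else {
    expr_const(stats::runif(1, config$const_range[1], config$const_range[2]))
  }
}

random_arith <- function(variables, config, depth, full) {
  if (depth <= 1 || (!full && stats::runif(1) < 0.3)) {
    return(random_leaf(variables, config))
  }
  op <- sample(arith_ops(config), 1)
  if (op %in% ARITH_UNARY) {
    expr_op(op, random_arith(variables, config, depth - 1, full))
  } else {
    expr_op(op, random_arith(variables, config, depth - 1, full),
            random_arith(variables, config, depth - 1, full))
  }
}

random_bool <- function(variables, config, depth, full) {
  if (depth <= 2 || (!full && stats::runif(1) < 0.4)) {
    return(expr_op(sample(COMPARISONS, 1),
                   random_arith(variables, config, depth - 1, full),
                   random_arith(variables, config, depth - 1, full)))
  }
  op <- sample(BOOL_BINARY, 1)
  expr_op(op, random_bool(variables, config, depth - 1, full),
          random_bool(variables, config, depth - 1, full))
}

# Ramped half-and-half rule set: depths cycle over 2..max_depth, alternating
# "full" and "grow" initialization.
random_rule <- function(variables, config, depth = NULL, full = NULL) {
  if (is.null(depth)) depth <- sample(2:config$max_depth, 1)
  if (is.null(full)) full <- stats::runif(1) < 0.5
  rule_set(random_bool(variables, config, depth, full),
           random_arith(variables, config, depth, full),
           random_arith(variables, config, depth, full))
}

# ---- tree surgery ---------------------------------------------------------

# Enumerate nodes of a rule set with their path and type.
rule_nodes <- function(ruleset) {
  acc <- list()
  walk <- function(node, path) {
    acc[[length(acc) + 1L]] <<- list(path = path, type = node_type(node))
    if (node$kind == "op") {
      for (i in seq_along(node$args)) {
        walk(node$args[[i]], c(path, i))
      }
    }
  }
  walk(ruleset$condition, c(1))
  walk(ruleset$then_expr, c(2))
  walk(ruleset$else_expr, c(3))
  acc
}

get_node <- function(ruleset, path) {
  node <- switch(path[1], ruleset$condition, ruleset$then_expr,
                 ruleset$else_expr)
  for (i in path[-1]) node <- node$args[[i]]
  node
}

set_node <- function(ruleset, path, new_node) {
  slot <- switch(path[1], "condition", "then_expr", "else_expr")
  rec <- function(node, rest) {
    if (length(rest) == 0) return(new_node)
    node$args[[rest[1]]] <- rec(node$args[[rest[1]]], rest[-1])
    node
  }
  ruleset[[slot]] <- rec(ruleset[[slot]], path[-1])
  ruleset
}

tree_depth <- function(node) {
  if (node$kind != "op") return(1L)
  1L + max(vapply(node$args, tree_depth, integer(1)))
}

rule_max_depth <- function(ruleset) {
  max(tree_depth(ruleset$condition), tree_depth(ruleset$then_expr),
      tree_depth(ruleset$else_expr))
}

# Typed subtree crossover: swap a random pair of same-type subtrees.
# Offspring deeper than max_depth + 2 are discarded in favour of parent 1.
crossover_rules <- function(a, b, config) {
  na <- rule_nodes(a)
  nb <- rule_nodes(b)
  types <- intersect(unique(vapply(na, `[[`, character(1), "type")),
                     unique(vapply(nb, `[[`, character(1), "type")))
  if (length(types) == 0) return(a)
  type <- sample(types, 1)
  pa <- Filter(function(x) x$type == type, na)
  pb <- Filter(function(x) x$type == type, nb)
  sa <- pa[[sample.int(length(pa), 1)]]
  sb <- pb[[sample.int(length(pb), 1)]]
  child <- set_node(a, sa$path, get_node(b, sb$path))
  if (rule_max_depth(child) > config$max_depth + 2) a else child
}

# Typed subtree mutation: replace a random subtree with a fresh random tree
# of the same type; constants additionally jitter with probability 0.5.
mutate_rule <- function(ruleset, variables, config) {
  nodes <- rule_nodes(ruleset)
  pick <- nodes[[sample.int(length(nodes), 1)]]
  node <- get_node(ruleset, pick$path)
  if (node$kind == "const" && stats::runif(1) < 0.5) {
    node$value <- node$value + stats::rnorm(1, 0, 0.1 * (1 + abs(node$value)))
    return(set_node(ruleset, pick$path, node))
  }
  depth <- sample(2:3, 1)
  repl <- if (pick$type == "bool") {
    random_bool(variables, config, depth, full = FALSE)
  } else {
    random_arith(variables, config, depth, full = FALSE)
  }
  set_node(ruleset, pick$path, repl)
}

# ---- fitness --------------------------------------------------------------

# Training RMSE of a rule's predictions on the original chla scale;
# non-finite fitness maps to +Inf (worst) so overflow never crashes a run.
rule_fitness <- function(ruleset, data, chla) {
  pred <- tryCatch(eval_rule(ruleset, data), error = function(e) NULL)
  if (is.null(pred) || any(!is.finite(pred))) return(Inf)
  f <- sqrt(mean((chla - pred)^2))
  if (!is.finite(f)) Inf else f
}

# ---- genetic programming --------------------------------------------------

#' Evolve rule sets by genetic programming
#'
#' Ramped half-and-half initialization, tournament selection, typed subtree
#' crossover and mutation, elitism of 1. Fitness is the training RMSE of a
#' rule's predictions (original ug/l scale); numerically degenerate rules
#' get worst fitness instead of crashing. Deterministic for a fixed seed.
#'
#' @param train Training [limno_series()] with `chla`.
#' @param config An [hea_config()].
#' @param variables Terminal variable set (default: series variables).
#' @param seed Seed for this run (default from config).
#' @return List: `best` rule set, `best_fitness`, `history` (best-of-
#'   generation fitness, non-increasing), `population`.
#' @export
gp_evolve <- function(train, config, variables = NULL, seed = config$seed) {
  if (nrow(train) == 0) stop("empty training series")
  if (is.null(variables)) variables <- series_variables(train)
  data <- as.data.frame(train)
  chla <- data$chla
  with_seed(seed, {
    depths <- rep(2:config$max_depth, length.out = config$population)
    fulls <- rep(c(TRUE, FALSE), length.out = config$population)
    pop <- lapply(seq_len(config$population), function(i)
      random_rule(variables, config, depths[i], fulls[i]))
    fit <- vapply(pop, rule_fitness, numeric(1), data, chla)
    history <- numeric(config$generations)
    tune <- function(rule) {
      ga_refine_core(rule, data, chla, config,
                     config$tune_population, config$tune_generations)
    }
    for (gen in seq_len(config$generations)) {
      best_idx <- which.min(fit)
      if (config$tune_elite && is.finite(fit[best_idx])) {
        tuned <- tune(pop[[best_idx]])
        pop[[best_idx]] <- tuned
        fit[best_idx] <- rule_fitness(tuned, data, chla)
        best_idx <- which.min(fit)
      }
      new_pop <- vector("list", config$population)
      new_pop[[1]] <- pop[[best_idx]]  # elitism
      tournament <- function() {
        idx <- sample.int(config$population, config$tournament_size,
                          replace = TRUE)
        pop[[idx[which.min(fit[idx])]]]
      }
      for (i in 2:config$population) {
        child <- tournament()
        if (stats::runif(1) < config$p_crossover) {
          child <- crossover_rules(child, tournament(), config)
        }
        if (stats::runif(1) < config$p_mutation) {
          child <- mutate_rule(child, variables, config)
        }
        if (config$p_tune > 0 && stats::runif(1) < config$p_tune) {
          child <- tune(child)
        }
        new_pop[[i]] <- child
      }
      pop <- new_pop
      fit <- vapply(pop, rule_fitness, numeric(1), data, chla)
      history[gen] <- min(fit)
    }
    best_idx <- which.min(fit)
    list(best = pop[[best_idx]], best_fitness = fit[best_idx],
         history = cummin(history), population = pop)
  })
}

# ---- GA constant refinement -----------------------------------------------

rule_constants <- function(ruleset) {
  nodes <- rule_nodes(ruleset)
  paths <- Filter(function(x) {
    get_node(ruleset, x$path)$kind == "const"
  }, nodes)
  list(paths = lapply(paths, `[[`, "path"),
       values = vapply(paths, function(x) get_node(ruleset, x$path)$value,
                       numeric(1)))
}

set_rule_constants <- function(ruleset, paths, values) {
  for (i in seq_along(paths)) {
    ruleset <- set_node(ruleset, paths[[i]], expr_const(values[i]))
  }
  ruleset
}

#' Refine a rule's numeric constants with a genetic algorithm
#'
#' The tree structure is frozen and only the constant vector evolves.
#' Recombination is the non-convex linear combination of `ga_parents`
#' parents: `child = sum(lambda_i * parent_i)` with the `lambda_i` drawn
#' from `ga_coef_range` and rescaled to sum to 1 (coefficients may fall
#' outside \[0, 1\], so children can extrapolate beyond the parents' hull).
#' Gaussian mutation perturbs single constants. The original constant vector
#' is seeded into the population and the best vector is kept (elitism), so
#' the returned rule's training RMSE never exceeds the input's. A rule with
#' no constants is returned unchanged with a message.
#'
#' @param ruleset A [rule_set()].
#' @param train Training [limno_series()] with `chla`.
#' @param config An [hea_config()].
#' @param seed Seed for this refinement.
#' @return The refined rule set.
#' @export
ga_refine_constants <- function(ruleset, train, config,
                                seed = config$seed) {
  cst <- rule_constants(ruleset)
  if (length(cst$values) == 0) {
    message("rule has no numeric constants; returned unchanged")
    return(ruleset)
  }
  data <- as.data.frame(train)
  with_seed(seed, {
    ga_refine_core(ruleset, data, data$chla, config,
                   config$ga_population, config$ga_generations)
  })
}

# GA constant optimization drawing from the caller's RNG stream; used both
# by ga_refine_constants (with a fresh seeded stream) and as the in-loop
# tuner of gp_evolve.
ga_refine_core <- function(ruleset, data, chla, config, n_pop, n_gen) {
  cst <- rule_constants(ruleset)
  k <- length(cst$values)
  if (k == 0) return(ruleset)
  eval_vec <- function(v) {
    rule_fitness(set_rule_constants(ruleset, cst$paths, v), data, chla)
  }
  pop <- vector("list", n_pop)
  pop[[1]] <- cst$values
  for (i in 2:n_pop) {
    # wide multiplicative + additive spread (sign flips allowed) so the
    # extrapolating crossover has a diverse hull to expand from
    pop[[i]] <- cst$values * stats::runif(k, -0.5, 2) +
      stats::rnorm(k, 0, 0.5)
  }
  fit <- vapply(pop, eval_vec, numeric(1))
  m <- config$ga_parents
  for (gen in seq_len(n_gen)) {
    new_pop <- vector("list", n_pop)
    new_pop[[1]] <- pop[[which.min(fit)]]
    for (i in 2:n_pop) {
      idx <- vapply(seq_len(m), function(...) {
        cand <- sample.int(n_pop, 2)
        cand[which.min(fit[cand])]
      }, integer(1))
      repeat {
        lambda <- stats::runif(m, config$ga_coef_range[1],
                               config$ga_coef_range[2])
        if (abs(sum(lambda)) > 0.1) break
      }
      lambda <- lambda / sum(lambda)
      child <- Reduce(`+`, Map(function(l, p) l * p, lambda, pop[idx]))
      if (stats::runif(1) < 0.5) {
        j <- sample.int(k, 1)
        child[j] <- child[j] + stats::rnorm(1, 0, 0.2 * (1 + abs(child[j])))
      }
      new_pop[[i]] <- child
    }
    pop <- new_pop
    fit <- vapply(pop, eval_vec, numeric(1))
  }
  best_fit <- min(fit)
  if (best_fit <= eval_vec(cst$values)) {
    set_rule_constants(ruleset, cst$paths, pop[[which.min(fit)]])
  } else {
    ruleset
  }
}

# ---- bit-mask variable selection ------------------------------------------

# Small GA over variable-inclusion masks; each mask is scored by the best
# fitness of a reduced-budget GP restricted to the masked-in terminals.
# All-zero masks are repaired to a random single variable.
evolve_variable_mask <- function(train, validate, candidates, config, seed) {
  proxy <- config
  proxy$population <- max(20, config$population %/% 4)
  proxy$generations <- max(5, config$generations %/% 4)
  score_data <- if (!is.null(validate) && nrow(validate) > 0) validate
                else train
  score_mask <- function(mask, s) {
    vars <- candidates[mask]
    res <- gp_evolve(train, proxy, variables = vars, seed = s)
    rule_fitness(res$best, as.data.frame(score_data), score_data$chla)
  }
  with_seed(seed, {
    np <- config$mask_population
    repair <- function(mask) {
      if (!any(mask)) mask[sample.int(length(mask), 1)] <- TRUE
      mask
    }
    pop <- lapply(seq_len(np), function(i)
      repair(stats::runif(length(candidates)) < 0.5))
    seeds <- sample.int(2^30, np * (config$mask_generations + 1))
    si <- 0
    next_seed <- function() {
      si <<- si + 1
      seeds[si]
    }
    fit <- vapply(pop, function(mk) score_mask(mk, next_seed()), numeric(1))
    for (gen in seq_len(config$mask_generations)) {
      new_pop <- vector("list", np)
      new_pop[[1]] <- pop[[which.min(fit)]]
      for (i in 2:np) {
        a <- pop[[sample.int(np, 1)]]
        b <- pop[[sample.int(np, 1)]]
        cross <- stats::runif(length(candidates)) < 0.5
        mask <- ifelse(cross, a, b)
        flip <- stats::runif(length(candidates)) < 0.1
        mask <- xor(mask, flip)
        new_pop[[i]] <- repair(mask)
      }
      pop <- new_pop
      fit <- vapply(pop, function(mk) score_mask(mk, next_seed()),
                    numeric(1))
    }
    pop[[which.min(fit)]]
  })
}

# ---- full multi-run pipeline ----------------------------------------------

#' Run the full hybrid evolutionary pipeline
#'
#' Per independent run: (optionally) a GA bit-mask selects the variable
#' subset exposed to the GP terminals, GP evolves a rule set on the training
#' set A, and the GA refines the best rule's constants. Across runs the rule
#' with minimal test-set (B) RMSE is reported. Per-run seeds derive from the
#' master seed, so results are reproducible.
#'
#' Note that selecting the final rule on test-set error follows the original
#' multi-run protocol; with `select_variables = TRUE` the variable mask is
#' scored on the validation set C when available, so variable selection
#' itself does not touch the test set.
#'
#' @param split A `limno_split` with non-empty `train_A` and `test_B`.
#' @param candidates Candidate variable names.
#' @param config An [hea_config()].
#' @return An `hea_result`: `runs` (data frame run, seed, train_rmse,
#'   test_rmse, variables, rule), `best` rule set, `best_test_rmse`,
#'   `best_train_rmse`, `selected_variables`.
#' @export
hea_run <- function(split, candidates = NULL, config = hea_config()) {
  if (nrow(split$train_A) == 0 || nrow(split$test_B) == 0) {
    stop("need non-empty training and test sets")
  }
  if (is.null(candidates)) candidates <- series_variables(split$train_A)
  train <- split$train_A
  test_df <- as.data.frame(split$test_B)
  run_rows <- vector("list", config$runs)
  best <- NULL
  for (run in seq_len(config$runs)) {
    run_seed <- derive_seed(config$seed, paste0("hea-run", run))
    vars <- candidates
    if (config$select_variables && length(candidates) > 1) {
      mask <- evolve_variable_mask(train, split$validate_C, candidates,
                                   config,
                                   derive_seed(run_seed, "mask"))
      vars <- candidates[mask]
    }
    gp <- gp_evolve(train, config, variables = vars,
                    seed = derive_seed(run_seed, "gp"))
    refined <- ga_refine_constants(gp$best, train, config,
                                   seed = derive_seed(run_seed, "ga"))
    train_rmse <- rule_fitness(refined, as.data.frame(train), train$chla)
    test_rmse <- rule_fitness(refined, test_df, test_df$chla)
    run_rows[[run]] <- data.frame(
      run = run, seed = run_seed, train_rmse = train_rmse,
      test_rmse = test_rmse, variables = paste(vars, collapse = "+"),
      rule = format_rule(refined), stringsAsFactors = FALSE)
    if (is.null(best) || test_rmse < best$test_rmse) {
      best <- list(rule = refined, test_rmse = test_rmse,
                   train_rmse = train_rmse, variables = vars)
    }
  }
  structure(list(runs = do.call(rbind, run_rows), best = best$rule,
                 best_test_rmse = best$test_rmse,
                 best_train_rmse = best$train_rmse,
                 selected_variables = best$variables),
            class = "hea_result")
}

#' @export
print.hea_result <- function(x, ...) {
  cat(sprintf("<hea_result> %d run(s); best test RMSE %.4f ug/l\n",
              nrow(x$runs), x$best_test_rmse))
  cat("  ", format_rule(x$best), "\n")
  invisible(x)
}
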