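## Independent brute-force oracles used across the suite. These stay
## deliberately naive and separate from the package implementation.

# sorted-row-means quantile normalization; ties in a column receive the
# mean of the pooled reference values at the tied ranks
bf_quantile_normalize <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    o <- order(x)
    assigned <- numeric(length(x))
    # each group of tied values receives the mean of the reference values
    # at the sorted positions the group occupies
    pos_by_value <- split(seq_along(x), x[o])
    for (ix in pos_by_value) assigned[ix] <- mean(ref[ix])
    out[o, j] <- assigned
  }
  out
}

# step-up FDR adjustment from the definition
bf_step_up <- function(p, by = FALSE) {
  n <- length(p)
  o <- order(p)
  cm <- if (by) sum(1 / seq_len(n)) else 1
  adj <- p[o] * cm * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# one-sided Fisher (enrichment) p as an explicit hypergeometric tail sum:
# overlap x, set sizes k (targets) and s (signature), universe N
bf_fisher_greater <- function(x, k, s, N) {
  support <- max(0, k + s - N):min(k, s)
  probs <- vapply(support, function(i) {
    exp(lchoose(s, i) + lchoose(N - s, k - i) - lchoose(N, k))
  }, numeric(1))
  sum(probs[support >= x])
}

# exhaustive stable-state scan over the FULL state space
bf_stable_states <- function(model, inputs, perturbation = NULL) {
  nm <- model$components$name
  maxl <- stats::setNames(model$components$max_level, nm)
  roles <- stats::setNames(model$components$role, nm)
  fixed <- c(as.list(inputs), as.list(perturbation %||% integer(0)))
  fixed <- fixed[!duplicated(names(fixed), fromLast = TRUE)]
  free <- setdiff(nm, names(fixed))
  grid <- do.call(expand.grid, c(lapply(maxl[free], function(m) 0:m),
                                 KEEP.OUT.ATTRS = FALSE))
  found <- list()
  for (i in seq_len(nrow(grid))) {
    st <- stats::setNames(integer(length(nm)), nm)
    for (f in names(fixed)) st[[f]] <- as.integer(fixed[[f]])
    for (f in free) st[[f]] <- as.integer(grid[i, f])
    if (identical(update_state(model, st, perturbation), st[nm])) {
      found[[length(found) + 1L]] <- st[nm]
    }
  }
  found
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random Boolean logical model with <= n_comp components for oracle scans
random_boolean_model <- function(n_comp, n_inputs = 1L, seed = 1L) {
  set.seed(seed)
  nm <- sprintf("c%02d", seq_len(n_comp))
  roles <- c(rep("input", n_inputs), rep("internal", n_comp - n_inputs))
  comps <- data.frame(name = nm, max_level = 1L, role = roles,
                      stringsAsFactors = FALSE)
  inter <- list(); rules <- list()
  for (target in nm[roles != "input"]) {
    k <- sample(1:3, 1L)
    regs <- sample(setdiff(nm, target), k)
    signs <- sample(c("activation", "inhibition"), k, replace = TRUE)
    for (j in seq_len(k)) {
      inter[[length(inter) + 1L]] <- data.frame(
        source = regs[j], target = target, sign = signs[j],
        threshold = 1L, stringsAsFactors = FALSE)
    }
    lit <- ifelse(signs == "activation",
                  paste0(regs, ">=1"),
                  paste0("NOT ", regs, ">=1"))
    op <- sample(c(" AND ", " OR "), 1L)
    rules[[length(rules) + 1L]] <- list(
      target = target, expression = paste(lit, collapse = op))
  }
  # inputs must not be interaction targets: guaranteed by construction
  logical_model(comps, do.call(rbind, inter), rules)
}

quick_config <- function(seed = 1L, ...) {
  args <- list(n_genes = 120L, n_mirnas = 20L,
               n_planted_regulations = 12L, targets_per_mirna = 4L,
               n_de_genes = 30L, n_de_mirnas = 8L, seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(simulation_config, args)
}
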