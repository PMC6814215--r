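# Independent oracles: scalar/brute-force re-implementations used to check
# the vectorized engine. Deliberately written against the definitions, not
# against the package internals.

# piecewise-linear membership, increasing specs only
oracle_convert <- function(x, fmin, fmax) {
  if (x < fmin) return(0)
  if (x > fmax) return(1)
  (x - fmin) / (fmax - fmin)
}

# recursive per-cell evaluation of a logic tree on named scalar raw inputs
oracle_eval_node <- function(tree, node_name, raw) {
  n <- tree$nodes[[node_name]]
  if (n$kind == "input") {
    x <- raw[[n$input_variable]]
    if (is.null(n$conversion)) return(x)
    return(oracle_convert(x, n$conversion$false, n$conversion$true))
  }
  kids <- vapply(as.character(unlist(n$children)),
                 function(ch) oracle_eval_node(tree, ch, raw), 0)
  switch(n$kind,
         convert = oracle_convert(kids[[1L]], n$conversion$false, n$conversion$true),
         and = min(kids),
         or = max(kids),
         # plain left-to-right scalar mean (no long-double accumulator)
         union = Reduce(`+`, kids) / length(kids))
}

oracle_eval_root <- function(tree, raw) oracle_eval_node(tree, tree$root, raw)

# random tree generator: proper tree (no shared children), depth <= max_depth
random_tree <- function(n_vars = 4, max_depth = 4) {
  counter <- 0
  new_name <- function(prefix) {
    counter <<- counter + 1
    paste0(prefix, counter)
  }
  nodes <- list()
  build <- function(depth) {
    if (depth >= max_depth || runif(1) < 0.3) {
      v <- sample.int(n_vars, 1)
      thr <- sort(runif(2))
      nm <- new_name("leaf")
      nodes[[nm]] <<- list(name = nm, kind = "input",
                           input_variable = paste0("v", v),
                           conversion = list(false = thr[1L], true = thr[2L]))
      return(nm)
    }
    kind <- sample(c("and", "or", "union", "convert"), 1,
                   prob = c(0.3, 0.3, 0.3, 0.1))
    nm <- new_name(kind)
    if (kind == "convert") {
      ch <- build(depth + 1)
      thr <- sort(runif(2))
      nodes[[nm]] <<- list(name = nm, kind = "convert", children = list(ch),
                           conversion = list(false = thr[1L], true = thr[2L]))
    } else {
      k <- sample(2:3, 1)
      ch <- lapply(seq_len(k), function(i) build(depth + 1))
      nodes[[nm]] <<- list(name = nm, kind = kind, children = ch)
    }
    nm
  }
  root <- build(1)
  if (nodes[[root]]$kind == "input") {
    # force at least one operator above a lone leaf
    v <- sample.int(n_vars, 1)
    thr <- sort(runif(2))
    nodes[["leaf_extra"]] <- list(name = "leaf_extra", kind = "input",
                                  input_variable = paste0("v", v),
                                  conversion = list(false = thr[1L], true = thr[2L]))
    nodes[["root_op"]] <- list(name = "root_op", kind = "and",
                               children = list(root, "leaf_extra"))
  }
  logic_tree(unname(nodes))
}

# brute-force percentile: sort + linear interpolation between order statistics
oracle_percentile <- function(v, p) {
  x <- sort(v)
  n <- length(x)
  h <- (n - 1) * p / 100 + 1
  lo <- floor(h)
  if (lo >= n) return(x[n])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

# brute-force per-cell argmax/argmin scan for member extremes
oracle_member_extremes <- function(stack) {
  grid <- stack$grid
  m <- which(grid$valid_mask)
  n <- length(stack$member_ids)
  at_max <- at_min <- numeric(n)
  for (cell in m) {
    v <- vapply(seq_len(n), function(i) stack$values[i, , ][cell], 0)
    at_max[v == max(v)] <- at_max[v == max(v)] + 1
    at_min[v == min(v)] <- at_min[v == min(v)] + 1
  }
  data.frame(member_id = stack$member_ids,
             frac_at_max = at_max / length(m), frac_at_min = at_min / length(m),
             stringsAsFactors = FALSE)
}
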