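# Internal helpers: classed conditions and small assertions.
# Condition classes mirror the pipeline's error taxonomy:
#   tripnet_config_error     - bad parameter / missing column
#   tripnet_validation_error - data violates an invariant
#   tripnet_state_error      - stage called out of order
#   tripnet_dependency_error - missing upstream artifact

stop_config <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "tripnet_config_error")
}

stop_validation <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "tripnet_validation_error")
}

stop_state <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "tripnet_state_error")
}

stop_dependency <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "tripnet_dependency_error")
}

assert_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    stop_config("`%s` must be a single number in [%g, %g], got %s",
                name, lo, hi, deparse(x))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x)) {
    stop_config("`%s` must be a single integer >= %d, got %s",
                name, min, deparse(x))
  }
  invisible(as.integer(x))
}

assert_columns <- function(df, cols, what = "input table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop_config("%s is missing required column(s): %s",
                what, paste(missing, collapse = ", "))
  }
  invisible(df)
}

# Sorted character vector with stable, locale-independent ordering.
sort_ids <- function(x) {
  sort(unique(as.character(x)), method = "radix")
}

# Edge density of an undirected simple graph given via a logical adjacency
# matrix restricted to `members` (character ids = rownames).
edge_density_of <- function(adj, members) {
  k <- length(members)
  if (k < 2L) return(1)
  sub <- adj[members, members, drop = FALSE]
  2 * sum(sub[upper.tri(sub)]) / (k * (k - 1))
}
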