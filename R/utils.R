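## Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG state
#'
#' Runs `expr` with `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so library functions with explicit `seed` arguments never
#' disturb the user's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

## Condition constructors: classed errors so the CLI can map them to exit codes.
ickg_input_error <- function(msg) {
  stop(structure(class = c("ickg_input_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

ickg_validation_error <- function(msg) {
  stop(structure(class = c("ickg_validation_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

ickg_nomap_error <- function(msg) {
  stop(structure(class = c("ickg_nomap_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

## Recognized node types for the knowledge graph.
NODE_TYPES <- c("gene", "disease", "cell_type", "pathway", "other")

## Edge directions materialized in the graph (no-association is never stored).
DIRECTIONS <- c("activate", "inhibit")

check_node_type <- function(x, what = "node_type") {
  bad <- setdiff(unique(x), NODE_TYPES)
  if (length(bad)) {
    ickg_validation_error(sprintf("unknown %s value(s): %s", what,
                                  paste(bad, collapse = ", ")))
  }
  invisible(x)
}

check_direction <- function(x) {
  bad <- setdiff(unique(x), DIRECTIONS)
  if (length(bad)) {
    ickg_validation_error(sprintf("unknown direction value(s): %s",
                                  paste(bad, collapse = ", ")))
  }
  invisible(x)
}

## Escape a literal string for use inside a PCRE pattern.
regex_escape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

## Word-boundary pattern for an entity surface: the surface must not be
## flanked by alphanumerics (hyphens and spaces inside the surface are kept).
surface_pattern <- function(surface) {
  paste0("(?<![A-Za-z0-9])", regex_escape(surface), "(?![A-Za-z0-9])")
}
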