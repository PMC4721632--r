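#' Partition of a system into parts
#'
#' A partition divides the `n` channels of a system into `m` disjoint,
#' non-empty blocks (parts) \eqn{M_1, \dots, M_m} that jointly cover all
#' channels. Integrated information measures quantify the information lost
#' when interactions *between* blocks are ignored.
#'
#' Blocks are stored in canonical form: members sorted ascending within each
#' block, blocks ordered by their smallest member. Indices are 1-based inside
#' R; the text serialization (see [parse_partition()]) is 0-based.
#'
#' @param blocks list of integer vectors, 1-based channel indices.
#' @param n total number of channels; defaults to the largest index present.
#' @return An object of class `"phi_partition"`: the canonical list of blocks
#'   with attributes `n` (number of channels) and `m` (number of blocks).
#' @examples
#' partition(list(c(1, 2), 3), n = 3)
#' atomic_partition(4)
#' @export
partition <- function(blocks, n = NULL) {
  if (!is.list(blocks) || length(blocks) == 0) {
    stop("blocks must be a non-empty list of index vectors", call. = FALSE)
  }
  blocks <- lapply(blocks, function(b) {
    b <- as.integer(b)
    if (length(b) == 0 || anyNA(b)) stop("empty or NA block", call. = FALSE)
    sort(b)
  })
  members <- unlist(blocks)
  if (anyDuplicated(members)) {
    stop("blocks must be disjoint; duplicated index ",
         members[duplicated(members)][1], call. = FALSE)
  }
  if (is.null(n)) n <- max(members)
  if (!setequal(members, seq_len(n))) {
    stop("blocks must cover exactly 1..", n, call. = FALSE)
  }
  blocks <- blocks[order(vapply(blocks, min, integer(1)))]
  structure(blocks, n = as.integer(n), m = length(blocks),
            class = "phi_partition")
}

#' @rdname partition
#' @export
atomic_partition <- function(n) {
  if (length(n) != 1 || is.na(n) || n < 1 || n != round(n)) {
    stop("n must be a positive integer", call. = FALSE)
  }
  partition(as.list(seq_len(n)), n = n)
}

#' @export
print.phi_partition <- function(x, ...) {
  cat(sprintf("Partition of %d channels into %d block(s): %s\n",
              attr(x, "n"), attr(x, "m"), format_partition(x)))
  invisible(x)
}

is_single_block <- function(p) attr(p, "m") == 1L

as_partition <- function(p, n) {
  if (inherits(p, "phi_partition")) {
    if (attr(p, "n") != n) {
      stop(sprintf("partition covers %d channels but the system has %d",
                   attr(p, "n"), n), call. = FALSE)
    }
    return(p)
  }
  if (is.character(p) && length(p) == 1) {
    if (identical(p, "atomic")) return(atomic_partition(n))
    return(parse_partition(p, n = n))
  }
  if (is.list(p)) return(partition(p, n = n))
  stop("cannot interpret 'partition' argument", call. = FALSE)
}

#' Parse and format the partition text representation
#'
#' The text form separates blocks with `/` and members with `,`, using
#' 0-based channel indices: `"0,1/2,3"` is the bipartition
#' \{\{1,2\},\{3,4\}\} in R's 1-based indexing.
#'
#' @param text partition string, e.g. `"0,1/2,3"`, or `"atomic"`.
#' @param n number of channels (required for `"atomic"`, otherwise inferred).
#' @return [parse_partition()] returns a `"phi_partition"`;
#'   [format_partition()] its 0-based string form.
#' @export
parse_partition <- function(text, n = NULL) {
  stopifnot(is.character(text), length(text) == 1)
  if (identical(text, "atomic")) {
    if (is.null(n)) stop("'atomic' requires n", call. = FALSE)
    return(atomic_partition(n))
  }
  blocks <- strsplit(strsplit(text, "/", fixed = TRUE)[[1]], ",", fixed = TRUE)
  blocks <- lapply(blocks, function(b) {
    v <- suppressWarnings(as.integer(trimws(b)))
    if (anyNA(v)) stop("non-integer index in partition string: ", text,
                       call. = FALSE)
    v + 1L
  })
  partition(blocks, n = n)
}

#' @rdname parse_partition
#' @param p a `"phi_partition"` object.
#' @export
format_partition <- function(p) {
  stopifnot(inherits(p, "phi_partition"))
  paste(vapply(p, function(b) paste(b - 1L, collapse = ","), character(1)),
        collapse = "/")
}

bell_number <- function(n) {
  # Bell triangle; exact for the small n allowed here
  row <- 1
  for (i in seq_len(n - 1)) {
    new <- numeric(i + 1)
    new[1] <- row[i]
    for (j in seq_len(i)) new[j + 1] <- new[j] + row[j]
    row <- new
  }
  row[length(row)]
}

#' Enumerate all partitions of a system
#'
#' Generates every set partition of `1..n` in canonical order. The number of
#' set partitions is the Bell number B(n), which grows super-exponentially,
#' so enumeration is guarded at `n <= 12` (B(12) = 4,213,597).
#'
#' @param n number of channels (at most 12).
#' @param include_trivial if `FALSE` (default) the single-block partition,
#'   under which every measure is identically zero, is omitted.
#' @return list of `"phi_partition"` objects.
#' @examples
#' length(enumerate_partitions(3))  # Bell(3) - 1 = 4
#' @export
enumerate_partitions <- function(n, include_trivial = FALSE) {
  if (n < 1 || n != round(n)) stop("n must be a positive integer", call. = FALSE)
  if (n > 12) {
    stop(sprintf(
      "refusing to enumerate %s set partitions of %d channels (n is capped at 12)",
      format(bell_number(n), big.mark = ","), n), call. = FALSE)
  }
  # restricted growth strings: channel i joins an existing block or opens a new one
  out <- list()
  recurse <- function(i, blocks) {
    if (i > n) {
      out[[length(out) + 1L]] <<- partition(blocks, n = n)
      return(invisible(NULL))
    }
    for (b in seq_along(blocks)) {
      blocks2 <- blocks
      blocks2[[b]] <- c(blocks2[[b]], i)
      recurse(i + 1L, blocks2)
    }
    recurse(i + 1L, c(blocks, list(i)))
  }
  recurse(2L, list(1L))
  if (!include_trivial) {
    out <- Filter(function(p) attr(p, "m") > 1L, out)
  }
  out
}

#' Minimum information partition search
#'
#' Evaluates an integrated-information measure over a set of candidate
#' partitions and returns the candidate with the smallest value — the
#' minimum information partition (MIP). No normalization across partition
#' granularities is applied (`normalize` is an optional hook); raw values
#' are compared, and ties are broken by canonical partition order.
#'
#' @param x a [lagged_gaussian()] or [discrete_joint()] system.
#' @param measure measure name: `"phi_star"`, `"phi_I"` or `"phi_H"`.
#' @param candidates list of partitions; defaults to all non-trivial
#'   partitions when the system has at most 12 channels.
#' @param normalize optional function `(value, partition) -> value` applied
#'   before comparison; default `NULL` compares raw values.
#' @return list with elements `partition`, `result` (the winning
#'   [measure_result]), and `table` (a data frame of every candidate's value;
#'   failed candidates carry `NA` and the error message).
#' @export
find_mip <- function(x, measure = "phi_star", candidates = NULL,
                     normalize = NULL) {
  n <- n_channels(x)
  if (is.null(candidates)) candidates <- enumerate_partitions(n)
  if (length(candidates) == 0) stop("no candidate partitions", call. = FALSE)
  fn <- switch(measure,
               phi_star = phi_star,
               phi_I = phi_I,
               phi_H = phi_H,
               stop("unknown measure: ", measure, call. = FALSE))
  vals <- numeric(length(candidates))
  notes <- character(length(candidates))
  results <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    res <- tryCatch(fn(x, candidates[[i]]), error = function(e) e)
    if (inherits(res, "error")) {
      vals[i] <- NA_real_
      notes[i] <- conditionMessage(res)
    } else {
      vals[i] <- res$value
      results[[i]] <- res
    }
  }
  if (all(is.na(vals))) {
    stop("every candidate partition failed to evaluate; first error: ",
         notes[1], call. = FALSE)
  }
  cmp <- vals
  if (!is.null(normalize)) {
    cmp <- mapply(normalize, vals, candidates)
  }
  best <- which(cmp == min(cmp, na.rm = TRUE))[1]  # ties: canonical order
  list(partition = candidates[[best]],
       result = results[[best]],
       table = data.frame(
         partition = vapply(candidates, format_partition, character(1)),
         value = vals,
         note = notes,
         stringsAsFactors = FALSE))
}

# number of channels of any supported system object
n_channels <- function(x) UseMethod("n_channels")

#' @export
n_channels.lagged_gaussian <- function(x) nrow(x$cov_past)

#' @export
n_channels.discrete_joint <- function(x) x$n_units
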