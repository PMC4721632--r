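#' Result of an integrated-information measure
#'
#' Container returned by [mutual_information()], [phi_star()], [phi_I()],
#' [phi_H()] and [max_entropy_phi()]. Values are in nats; use
#' [in_bits()] or the serialized `value_bits` field for bits.
#'
#' @param measure_name one of `"phi_star"`, `"phi_I"`, `"phi_H"`,
#'   `"mutual_information"`, `"phi_max_entropy"`.
#' @param value the measure, in nats.
#' @param partition the [partition()] used (`NULL` for mutual information).
#' @param whole_information whole-system mutual information I, nats.
#' @param mismatched_information I*, the information recoverable under
#'   mismatched (partitioned) decoding, nats; `NA` unless relevant.
#' @param beta_star the decoding tilt that maximizes I*; `NA` unless relevant.
#' @param part_terms per-block terms (per-part I, or per-part conditional
#'   entropies), ordered as the partition's blocks.
#' @return An object of class `"measure_result"`.
#' @export
measure_result <- function(measure_name, value, partition = NULL,
                           whole_information = NA_real_,
                           mismatched_information = NA_real_,
                           beta_star = NA_real_,
                           part_terms = numeric(0)) {
  structure(list(measure_name = measure_name,
                 value = value,
                 whole_information = whole_information,
                 mismatched_information = mismatched_information,
                 beta_star = beta_star,
                 part_terms = part_terms,
                 partition = partition),
            class = "measure_result")
}

#' @export
print.measure_result <- function(x, ...) {
  cat(sprintf("%s = %.6g nats (%.6g bits)\n",
              x$measure_name, x$value, x$value / log(2)))
  if (is.finite(x$whole_information)) {
    cat(sprintf("  whole-system information I = %.6g nats\n",
                x$whole_information))
  }
  if (is.finite(x$mismatched_information)) {
    cat(sprintf("  mismatched-decoding information I* = %.6g nats (beta* = %.6g)\n",
                x$mismatched_information, x$beta_star))
  }
  if (!is.null(x$partition)) {
    cat("  partition:", format_partition(x$partition), "\n")
  }
  invisible(x)
}

#' Convert a measure value from nats to bits
#'
#' @param x a `"measure_result"` or a numeric value in nats.
#' @return numeric value in bits.
#' @export
in_bits <- function(x) {
  v <- if (inherits(x, "measure_result")) x$value else x
  v / log(2)
}

#' Serialize a measure result to JSON
#'
#' Writes `measure_name`, `value_nats`, `value_bits`, `beta_star`,
#' `whole_information`, `mismatched_information`, `part_terms` and the
#' partition as a 0-based list of lists.
#'
#' @param x a `"measure_result"`.
#' @param path file path.
#' @export
write_measure_result <- function(x, path) {
  stopifnot(inherits(x, "measure_result"))
  doc <- list(
    measure_name = x$measure_name,
    value_nats = x$value,
    value_bits = x$value / log(2),
    beta_star = if (is.finite(x$beta_star)) x$beta_star else NULL,
    whole_information = x$whole_information,
    mismatched_information =
      if (is.finite(x$mismatched_information)) x$mismatched_information else NULL,
    part_terms = x$part_terms,
    partition = if (!is.null(x$partition)) {
      lapply(x$partition, function(b) I(b - 1L))  # I() keeps singleton blocks as arrays
    } else NULL)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
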