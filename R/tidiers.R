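#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an LSI fit
#'
#' One row per component: singular value, variance share, depth correlation
#' and the depth flag.
#'
#' @param x A `phr_lsi`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.phr_lsi <- function(x, ...) {
  tibble::tibble(
    component = colnames(x$embedding),
    singular_value = x$d,
    variance_share = x$d^2 / sum(x$d^2),
    depth_cor = as.numeric(x$depth_cor),
    depth_flagged = x$flagged
  )
}

#' @rdname tidy.phr_lsi
#' @export
glance.phr_lsi <- function(x, ...) {
  tibble::tibble(
    n_components = ncol(x$embedding),
    n_depth_flagged = sum(x$flagged),
    top_singular_share = x$d[1]^2 / sum(x$d^2)
  )
}

#' Tidy a link table
#'
#' @param x A `phr_links`.
#' @param ... Unused.
#' @return The link tibble (one row per ADT-peak-gene link).
#' @export
tidy.phr_links <- function(x, ...) x$table

#' @rdname tidy.phr_links
#' @export
glance.phr_links <- function(x, ...) {
  tibble::tibble(
    n_links = nrow(x$table),
    n_adts = length(unique(x$table$adt)),
    n_peaks = length(unique(x$table$peak_id)),
    n_genes = length(unique(x$table$gene)),
    n_activating = sum(x$table$class == "activating"),
    n_repressive = sum(x$table$class == "repressive")
  )
}

#' Tidy a differential accessibility table
#'
#' @param x A `phr_dar`.
#' @param ... Unused.
#' @return A plain tibble.
#' @export
tidy.phr_dar <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidy.phr_dar
#' @export
glance.phr_dar <- function(x, ...) {
  tibble::tibble(
    n_tested = nrow(x),
    n_dar = sum(x$dar),
    n_excluded = attr(x, "n_excluded") %||% NA_integer_
  )
}
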