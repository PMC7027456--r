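#' Canonical stream component names
#'
#' Process streams are represented as named vectors of component masses (kg).
#' The canonical component set is the smallest one that expresses every
#' stream composition the model tracks: process water, the antimicrobial
#' protein product (AMP), soluble host impurities (host proteins and other
#' solubles), insoluble solids (fibre, cell debris), and buffer salts.
#' Arbitrary extra components are allowed; unknown components simply ride
#' along in the mass balance.
#'
#' @format Character vector of component names.
#' @export
tea_components <- c("water", "amp", "impurity", "solids", "salts")

#' Construct a process stream
#'
#' A stream is a material flow through the facility, held as a named vector
#' of non-negative component masses in kg. The total mass is always the sum
#' of the components; it is stored for convenience and revalidated on
#' construction.
#'
#' @param components Named numeric vector of component masses (kg).
#'   Names are free, but see [tea_components] for the canonical set.
#' @param phase Free-text phase label (e.g. "aqueous extract", "powder").
#' @return An object of class `tea_stream`.
#' @examples
#' harvest <- stream(c(water = 8948.8, amp = 9.52, impurity = 85.68,
#'                     solids = 476), phase = "harvested biomass")
#' stream_mass(harvest)
#' @export
stream <- function(components, phase = "aqueous") {
  if (is.null(names(components)) || any(!nzchar(names(components)))) {
    stop("stream components must be a fully named numeric vector", call. = FALSE)
  }
  components <- vapply(split(unname(components), names(components)), sum,
                       numeric(1))
  out <- structure(
    list(components = components,
         total_mass = sum(components),
         phase = phase),
    class = "tea_stream")
  validate_stream(out)
  out
}

#' Validate a stream object
#'
#' Checks the stream invariants: all component masses non-negative and the
#' stored total equal to the component sum within 1e-9 relative tolerance.
#'
#' @param x A `tea_stream`.
#' @return `x`, invisibly; errors on violation.
#' @export
validate_stream <- function(x) {
  stopifnot(inherits(x, "tea_stream"))
  thr <- -1e-9 * max(1, abs(x$total_mass))
  if (any(x$components < thr)) {
    bad <- names(x$components)[x$components < thr]
    stop("negative component mass in stream: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  rel <- abs(x$total_mass - sum(x$components)) / max(1, abs(x$total_mass))
  if (rel > 1e-9) {
    stop("stream total_mass does not equal component sum", call. = FALSE)
  }
  invisible(x)
}

#' Total mass of a stream
#' @param x A `tea_stream`.
#' @return Total mass in kg.
#' @export
stream_mass <- function(x) {
  stopifnot(inherits(x, "tea_stream"))
  x$total_mass
}

#' Mass of one component in a stream
#'
#' @param x A `tea_stream`.
#' @param component Component name; components absent from the stream have
#'   zero mass.
#' @return Mass in kg.
#' @export
stream_component <- function(x, component) {
  stopifnot(inherits(x, "tea_stream"))
  m <- unname(x$components[component])
  m[is.na(m)] <- 0
  m
}

#' Mass fraction of one component in a stream (percent)
#' @inheritParams stream_component
#' @return Percent of total stream mass.
#' @export
stream_pct <- function(x, component) {
  if (stream_mass(x) <= 0) return(0)
  100 * stream_component(x, component) / stream_mass(x)
}

#' @export
print.tea_stream <- function(x, ...) {
  cat(sprintf("<tea_stream> %s: %.6g kg\n", x$phase, x$total_mass))
  comp <- x$components[order(-x$components)]
  for (nm in names(comp)) {
    cat(sprintf("  %-10s %12.6g kg  (%6.3f%%)\n", nm, comp[[nm]],
                100 * comp[[nm]] / max(x$total_mass, .Machine$double.eps)))
  }
  invisible(x)
}

#' @export
as.data.frame.tea_stream <- function(x, ...) {
  data.frame(component = names(x$components),
             mass_kg = unname(x$components),
             pct = 100 * unname(x$components) /
               max(x$total_mass, .Machine$double.eps),
             row.names = NULL)
}

# arithmetic helpers used by the propagation engine -------------------------

# merge two named component vectors by summing shared names
merge_components <- function(a, b) {
  nms <- union(names(a), names(b))
  out <- stats::setNames(numeric(length(nms)), nms)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  out
}

zero_components <- function(nms) stats::setNames(numeric(length(nms)), nms)
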