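#' Define a unit operation
#'
#' A unit operation is described by per-component transfer fractions (the
#' fraction of each component in the combined input pool that reports to the
#' product stream) plus optional added inputs (buffers, wash solutions)
#' whose mass is a fixed ratio to a declared basis quantity of the incoming
#' stream. Everything not transferred to product leaves in the waste stream,
#' so mass is conserved component-wise at every stage:
#' `input + additions = product + waste`.
#'
#' Added inputs either mix into the component pool before the transfer split
#' (`to_product = FALSE`, e.g. extraction buffer pressed together with the
#' biomass) or pass directly into the product stream (`to_product = TRUE`,
#' e.g. the elution buffer that carries the product off a chromatography
#' column while the feed liquid goes to waste).
#'
#' @param name Identifier for the operation.
#' @param product_transfer Named numeric vector of transfer fractions in
#'   \[0, 1\] (component -> fraction to product). Components of the input not
#'   named here receive `default_transfer`.
#' @param added_inputs List of additions, each a list with elements `name`,
#'   `ratio` (kg added per kg of basis), `basis` (`"total"` or a component
#'   name of the incoming stream), `composition` (named fractions summing to
#'   1) and optional `to_product` (default `FALSE`).
#' @param default_transfer Transfer fraction for unnamed components.
#' @param sizing_basis `"volume"` or `"product_mass"`; records whether the
#'   equipment behind this step is sized by throughput volume or by product
#'   quantity (drives cost scaling, not the mass balance).
#' @return An object of class `tea_unit_op`.
#' @examples
#' extraction <- unit_op("screw press extraction",
#'   product_transfer = c(amp = 0.94, impurity = 0.8, solids = 0.02,
#'                        water = 0.81, salts = 0.81),
#'   added_inputs = list(list(name = "extraction buffer", ratio = 0.5,
#'                            basis = "total",
#'                            composition = c(water = 0.995, salts = 0.005))))
#' @export
unit_op <- function(name, product_transfer = numeric(),
                    added_inputs = list(), default_transfer = 0,
                    sizing_basis = c("volume", "product_mass")) {
  sizing_basis <- match.arg(sizing_basis)
  if (length(product_transfer) &&
      (is.null(names(product_transfer)) || any(!nzchar(names(product_transfer))))) {
    stop("product_transfer must be a named vector", call. = FALSE)
  }
  if (any(product_transfer < 0) || any(product_transfer > 1 + 1e-12)) {
    stop("transfer fractions for op '", name, "' must lie in [0, 1]",
         call. = FALSE)
  }
  if (default_transfer < 0 || default_transfer > 1) {
    stop("default_transfer must lie in [0, 1]", call. = FALSE)
  }
  for (ad in added_inputs) {
    if (is.null(ad$name) || is.null(ad$ratio) || is.null(ad$composition)) {
      stop("each added input needs name, ratio and composition", call. = FALSE)
    }
    if (ad$ratio < 0) stop("added input ratio must be >= 0", call. = FALSE)
    if (abs(sum(ad$composition) - 1) > 1e-9) {
      stop("added input '", ad$name, "' composition must sum to 1",
           call. = FALSE)
    }
  }
  structure(list(name = name,
                 product_transfer = product_transfer,
                 added_inputs = added_inputs,
                 default_transfer = default_transfer,
                 sizing_basis = sizing_basis),
            class = "tea_unit_op")
}

#' @export
print.tea_unit_op <- function(x, ...) {
  cat(sprintf("<tea_unit_op> %s (sized by %s)\n", x$name, x$sizing_basis))
  if (length(x$product_transfer)) {
    cat("  transfer to product:\n")
    for (nm in names(x$product_transfer)) {
      cat(sprintf("    %-10s %.5f\n", nm, x$product_transfer[[nm]]))
    }
  }
  for (ad in x$added_inputs) {
    cat(sprintf("  + %s: %.4g kg/kg %s%s\n", ad$name, ad$ratio, ad$basis,
                if (isTRUE(ad$to_product)) " (direct to product)" else ""))
  }
  invisible(x)
}

basis_mass <- function(input, basis) {
  if (identical(basis, "total")) return(stream_mass(input))
  if (!basis %in% names(input$components)) {
    stop("unknown basis component '", basis, "' for added input", call. = FALSE)
  }
  stream_component(input, basis)
}

#' Propagate a stream through one unit operation
#'
#' Applies the additions and transfer split of a unit operation to an input
#' stream and returns the stage record: input, product and waste streams and
#' the AMP recovery of the stage. Component-wise conservation
#' (`input + additions = product + waste`) holds by construction and is
#' re-checked before returning.
#'
#' @param op A [unit_op()].
#' @param input A [stream()].
#' @return An object of class `tea_stage` with elements `op_name`,
#'   `input_stream`, `additions`, `product_stream`, `waste_stream` and
#'   `amp_recovery`.
#' @export
propagate <- function(op, input) {
  stopifnot(inherits(op, "tea_unit_op"))
  validate_stream(input)

  added <- zero_components(character(0))
  direct <- zero_components(character(0))
  for (ad in op$added_inputs) {
    mass <- ad$ratio * basis_mass(input, ad$basis)
    contrib <- ad$composition * mass
    if (isTRUE(ad$to_product)) {
      direct <- merge_components(direct, contrib)
    } else {
      added <- merge_components(added, contrib)
    }
  }
  pool <- merge_components(input$components, added)

  tr <- stats::setNames(rep(op$default_transfer, length(pool)), names(pool))
  known <- intersect(names(op$product_transfer), names(pool))
  tr[known] <- op$product_transfer[known]

  product_pool <- pool * tr
  waste <- pool - product_pool
  product <- merge_components(product_pool, direct)

  product_s <- stream(product, phase = paste(op$name, "product"))
  waste_s <- stream(waste, phase = paste(op$name, "waste"))

  total_add <- merge_components(added, direct)
  lhs <- merge_components(input$components, total_add)
  rhs <- merge_components(product_s$components, waste_s$components)
  if (max(abs(merge_components(lhs, -rhs))) >
      1e-9 * max(1, stream_mass(input))) {
    stop("internal mass-balance failure in op '", op$name, "'", call. = FALSE)
  }

  amp_in <- stream_component(input, "amp") +
    sum(total_add[names(total_add) == "amp"])
  amp_out <- stream_component(product_s, "amp")
  rec <- if (amp_in > 0) amp_out / amp_in else NA_real_

  structure(list(op_name = op$name,
                 input_stream = input,
                 additions = if (length(total_add)) {
                   stream(total_add, phase = paste(op$name, "additions"))
                 } else NULL,
                 product_stream = product_s,
                 waste_stream = waste_s,
                 amp_recovery = rec),
            class = "tea_stage")
}

#' @export
print.tea_stage <- function(x, ...) {
  cat(sprintf("<tea_stage> %s: %.6g kg in -> %.6g kg product (AMP recovery %.4f)\n",
              x$op_name, stream_mass(x$input_stream),
              stream_mass(x$product_stream), x$amp_recovery))
  invisible(x)
}

#' Run an ordered chain of unit operations
#'
#' Feeds the product stream of each stage into the next. The cumulative AMP
#' recovery of the chain is the product of the per-stage recoveries.
#'
#' @param ops Non-empty list of [unit_op()] objects, in processing order.
#' @param input The harvest [stream()] entering the first operation.
#' @return A list of `tea_stage` records with class `tea_chain_result`.
#' @export
run_chain <- function(ops, input) {
  if (!length(ops)) stop("operation chain must be non-empty", call. = FALSE)
  records <- vector("list", length(ops))
  current <- input
  for (i in seq_along(ops)) {
    records[[i]] <- propagate(ops[[i]], current)
    current <- records[[i]]$product_stream
  }
  structure(records, class = "tea_chain_result")
}

#' Cumulative AMP recovery of a chain run
#' @param records A `tea_chain_result` from [run_chain()].
#' @return Product of per-stage AMP recoveries.
#' @export
chain_recovery <- function(records) {
  prod(vapply(records, function(r) r$amp_recovery, numeric(1)))
}

#' Tabulate a chain run, one row per stage
#'
#' Mirrors the per-batch stream table of a batch report: stream mass leaving
#' each stage with its AMP and host-impurity content and per-stage recovery.
#'
#' @param records A `tea_chain_result`.
#' @return A data.frame with columns `stage`, `op`, `mass_kg`, `pct_amp`,
#'   `pct_impurity`, `amp_kg`, `stage_recovery`.
#' @export
stage_table <- function(records) {
  data.frame(
    stage = seq_along(records),
    op = vapply(records, function(r) r$op_name, character(1)),
    mass_kg = vapply(records, function(r) stream_mass(r$product_stream),
                     numeric(1)),
    pct_amp = vapply(records, function(r) stream_pct(r$product_stream, "amp"),
                     numeric(1)),
    pct_impurity = vapply(records, function(r)
      stream_pct(r$product_stream, "impurity"), numeric(1)),
    amp_kg = vapply(records, function(r)
      stream_component(r$product_stream, "amp"), numeric(1)),
    stage_recovery = vapply(records, function(r) r$amp_recovery, numeric(1)),
    row.names = NULL)
}
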