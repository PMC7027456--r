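# JSON serialization of scenario configurations. JSON keeps doubles at full
# precision, so write -> read is the identity on every numeric field.

config_to_list <- function(config) {
  op_to_list <- function(op) {
    list(name = op$name,
         product_transfer = as.list(op$product_transfer),
         default_transfer = op$default_transfer,
         sizing_basis = op$sizing_basis,
         added_inputs = lapply(op$added_inputs, function(ad) {
           list(name = ad$name, ratio = ad$ratio, basis = ad$basis,
                to_product = isTRUE(ad$to_product),
                composition = as.list(ad$composition))
         }))
  }
  df_to_rows <- function(df) {
    lapply(seq_len(NROW(df)), function(i) as.list(df[i, , drop = FALSE]))
  }
  list(scenario = config$scenario,
       demand_kg = config$demand_kg,
       batches = config$batches,
       overall_recovery = config$overall_recovery,
       host = unclass(config$host),
       schedule = config$schedule,
       prices = config$prices,
       chain = lapply(config$chain, op_to_list),
       ledger = df_to_rows(config$ledger),
       equipment = df_to_rows(config$equipment),
       expected = config$expected)
}

list_to_config <- function(x) {
  num_or_na <- function(v) if (is.null(v) || length(v) == 0) NA_real_ else
    as.numeric(v)
  op_from_list <- function(o) {
    structure(list(
      name = o$name,
      product_transfer = unlist(o$product_transfer),
      added_inputs = lapply(o$added_inputs, function(ad) {
        list(name = ad$name, ratio = ad$ratio, basis = ad$basis,
             to_product = isTRUE(ad$to_product),
             composition = unlist(ad$composition))
      }),
      default_transfer = o$default_transfer %||% 0,
      sizing_basis = o$sizing_basis %||% "volume"),
      class = "tea_unit_op")
  }
  rows_to_df <- function(rows, numeric_cols) {
    do.call(rbind, lapply(rows, function(r) {
      for (col in numeric_cols) r[[col]] <- num_or_na(r[[col]])
      as.data.frame(r[!vapply(r, is.null, logical(1))],
                    stringsAsFactors = FALSE)
    }))
  }
  structure(list(
    scenario = x$scenario,
    demand_kg = x$demand_kg,
    batches = x$batches,
    overall_recovery = x$overall_recovery,
    host = structure(x$host, class = "tea_host"),
    schedule = x$schedule,
    prices = x$prices,
    chain = lapply(x$chain, op_from_list),
    ledger = rows_to_df(x$ledger, c("annual_quantity", "unit_price",
                                    "annual_cost")),
    equipment = rows_to_df(x$equipment, character(0)),
    expected = x$expected),
    class = "tea_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a scenario configuration to a JSON file
#'
#' @param config A `tea_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "tea_config"))
  jsonlite::write_json(config_to_list(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

config_schema <- list(
  top = c("scenario", "demand_kg", "batches", "overall_recovery", "host",
          "schedule", "prices", "chain", "ledger", "equipment"),
  host = c("name", "fw_per_plant_g", "expression_g_per_kg", "tsp_fraction",
           "seeds_per_tray", "plants_per_tray", "induction_biomass_factor"),
  schedule = c("operating_days_per_year", "upstream_cycle_days",
               "downstream_cycle_days"))

#' Read and schema-check a scenario configuration
#'
#' Parses a JSON configuration file and verifies the required fields are
#' present; schema errors name the offending field path (e.g.
#' `host.expression_g_per_kg`).
#'
#' @param path Path to a configuration written by [write_config()].
#' @return A `tea_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  x <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE,
                       simplifyDataFrame = FALSE, simplifyMatrix = FALSE),
    error = function(e) stop("config parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  errs <- character(0)
  miss <- setdiff(config_schema$top, names(x))
  errs <- c(errs, miss)
  if ("host" %in% names(x)) {
    errs <- c(errs, paste0("host.",
                           setdiff(config_schema$host, names(x$host)),
                           recycle0 = TRUE))
  }
  if ("schedule" %in% names(x)) {
    errs <- c(errs, paste0("schedule.",
                           setdiff(config_schema$schedule,
                                   names(x$schedule)),
                           recycle0 = TRUE))
  }
  if (length(errs)) {
    stop("config schema errors, missing field(s): ",
         paste(errs, collapse = ", "), call. = FALSE)
  }
  if (!length(x$chain)) stop("config schema errors, missing field(s): chain",
                             call. = FALSE)
  list_to_config(x)
}
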