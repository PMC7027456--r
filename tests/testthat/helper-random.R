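# shared generators for property-style tests

random_stream <- function(n_components = 5) {
  nms <- paste0("c", seq_len(n_components))
  nms[2] <- "amp"   # keep an AMP component so recoveries are defined
  stream(stats::setNames(stats::runif(n_components, 0, 100), nms))
}

random_op <- function(input, p_addition = 0.5) {
  nms <- names(input$components)
  adds <- list()
  if (stats::runif(1) < p_addition) {
    comp <- stats::runif(2)
    adds <- list(list(name = "solution",
                      ratio = stats::runif(1, 0, 2),
                      basis = sample(c("total", nms), 1),
                      to_product = stats::runif(1) < 0.3,
                      composition = stats::setNames(comp / sum(comp),
                                                    sample(nms, 2))))
  }
  unit_op("random op",
          product_transfer = stats::setNames(stats::runif(length(nms)), nms),
          added_inputs = adds)
}

# independent component-by-component conservation check: explicit loop and
# scalar sums, sharing no code with the propagation engine
conservation_gap <- function(stage) {
  nms <- unique(c(names(stage$input_stream$components),
                  if (!is.null(stage$additions))
                    names(stage$additions$components),
                  names(stage$product_stream$components),
                  names(stage$waste_stream$components)))
  gaps <- numeric(0)
  for (nm in nms) {
    inn <- 0
    if (nm %in% names(stage$input_stream$components))
      inn <- inn + stage$input_stream$components[[nm]]
    if (!is.null(stage$additions) &&
        nm %in% names(stage$additions$components))
      inn <- inn + stage$additions$components[[nm]]
    out <- 0
    if (nm %in% names(stage$product_stream$components))
      out <- out + stage$product_stream$components[[nm]]
    if (nm %in% names(stage$waste_stream$components))
      out <- out + stage$waste_stream$components[[nm]]
    gaps <- c(gaps, abs(inn - out))
  }
  max(gaps)
}
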