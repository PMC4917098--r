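#' Read a paired sample from a delimited text file
#'
#' @param path Path to a TSV/CSV/whitespace-delimited file with at least two
#'   numeric columns.
#' @param delim Field delimiter; `NULL` sniffs the first line (tab, then
#'   comma, then whitespace).
#' @param header Logical; `NULL` auto-detects by checking whether the first
#'   line parses as numbers.
#' @param columns Length-2 vector of column indices or names for x and y.
#' @return A [paired_sample()]. Non-numeric or missing cells abort with the
#'   offending row numbers.
#' @export
read_pairs <- function(path, delim = NULL, header = NULL,
                       columns = c(1L, 2L)) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (is.null(delim))
    delim <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  if (is.null(header)) {
    fields <- strsplit(first, if (delim == "") "[[:space:]]+" else delim,
                       fixed = delim != "")[[1]]
    header <- anyNA(suppressWarnings(as.numeric(fields)))
  }
  df <- tryCatch(
    utils::read.table(path, sep = delim, header = header,
                      stringsAsFactors = FALSE, fill = FALSE,
                      blank.lines.skip = TRUE),
    error = function(e) stop_invalid("parse error in ", path, ": ",
                                     conditionMessage(e)))
  if (ncol(df) < 2L) stop_invalid("need at least 2 columns, found ", ncol(df))
  if (nrow(df) < 2L) stop_invalid("need at least 2 data rows, found ", nrow(df))
  xy <- lapply(columns, function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop_invalid("non-numeric or missing values in column ", col,
                   " at row(s) ", paste(utils::head(bad, 5), collapse = ", "))
    v
  })
  paired_sample(xy[[1]], xy[[2]])
}

#' End-to-end MIC run with serializable output
#'
#' Reads or generates a sample, computes the MIC with the requested
#' algorithm, and returns (optionally JSON-serialized) results including
#' the best grid shape and the MCN in both epsilon modes.
#'
#' @param input A file path, a [paired_sample()], or a list
#'   `list(generator = "independent"|catalog name, n = ..., noise_level
#'   = ..., seed = ...)`.
#' @param algorithm `"chimic"` or `"approxmaxmi"`.
#' @param termination A [termination_config()] (ChiMIC only).
#' @param config An [optimizer_config()].
#' @param format `"list"` or `"json"` (17 significant digits).
#' @return A named list (or its JSON string) with `mic`, `best_shape`,
#'   `mcn_eps0`, `mcn_one_minus_mic`, `algorithm`, `n` and the parameters
#'   used.
#' @export
run_mic <- function(input, algorithm = c("chimic", "approxmaxmi"),
                    termination = termination_config(),
                    config = optimizer_config(),
                    format = c("list", "json")) {
  algorithm <- match.arg(algorithm)
  format <- match.arg(format)
  sample <-
    if (is.character(input)) read_pairs(input)
    else if (is.list(input) && !is.null(input$generator)) {
      gen <- input$generator
      if (identical(gen, "independent"))
        independent_pair(input$n, seed = input$seed)
      else
        sample_function(gen, input$n,
                        noise_level = input$noise_level %||% 0,
                        seed = input$seed)
    } else as_paired_sample(input)
  res <- if (algorithm == "chimic")
    chimic_mic(sample, termination, config)
  else
    approx_max_mi(sample, config)
  out <- list(
    algorithm = res$algorithm,
    n = res$n,
    mic = res$mic,
    best_shape = as.integer(res$best_shape),
    mcn_eps0 = mcn(res, epsilon = 0),
    mcn_one_minus_mic = mcn(res, mode = "one-minus-mic"),
    parameters = list(a = config$a, c = config$c,
                      budget_rounding = config$budget_rounding,
                      alpha = termination$alpha,
                      apply_b_cap = termination$apply_b_cap),
    package_version = as.character(utils::packageVersion("chimic")))
  if (format == "json")
    jsonlite::toJSON(out, auto_unbox = TRUE, digits = 17)
  else out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a paired sample as TSV
#'
#' Two named columns `x`, `y` at full double precision.
#'
#' @param sample A [paired_sample()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(sample, path) {
  sample <- as_paired_sample(sample)
  df <- data.frame(x = sprintf("%.17g", sample$x),
                   y = sprintf("%.17g", sample$y))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
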