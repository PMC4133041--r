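# Serialization: theory curves and conditional curves to CSV (RFC 4180 body
# with '#' metadata header lines), summaries to JSON, run configuration to
# and from YAML.

metadata_header <- function(params, extra = list()) {
  fields <- c(list(package = paste0("evorescue ",
                                    as.character(utils::packageVersion("evorescue"))),
                   N0 = params$N0, r = params$r, s = params$s, u = params$u,
                   k = params$k, p0 = params$p0, K = params$K,
                   time_convention = params$time_convention),
              extra)
  paste0("# ", names(fields), " = ", vapply(fields, function(x)
    paste(format(x), collapse = " "), character(1)))
}

#' Write a curve table to CSV with a self-describing header
#'
#' Parameters, seeds, and the package version are embedded as `#` comment
#' lines above an RFC 4180 body; [read_rescue_csv()] reads them back.
#'
#' @param x A [theory_curve()] or [conditional_moments()] tibble.
#' @param path Output file.
#' @param extra Named list of extra metadata fields (e.g. `seed`).
#' @return `path`, invisibly.
#' @export
write_rescue_csv <- function(x, path, extra = list()) {
  params <- attr(x, "params")
  hdr <- if (!is.null(params)) metadata_header(params, extra) else character()
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(as.data.frame(x), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rescue_csv
#' @param path Input file.
#' @return For `read_rescue_csv()`: the tibble, with the metadata in
#'   attribute `"metadata"`.
#' @export
read_rescue_csv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ln), "\\s*=\\s*")[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- utils::type.convert(kv[2],
                                                              as.is = TRUE)
  }
  body <- utils::read.csv(text = lines[!startsWith(lines, "#")])
  out <- tibble::as_tibble(body)
  attr(out, "metadata") <- meta
  out
}

#' Write a rescue summary (or any one-row tibble) to JSON
#'
#' @param x A tibble or named list.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_rescue_json <- function(x, path) {
  jsonlite::write_json(as.list(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

config_fields <- c("N0", "r", "s", "u", "k", "p0", "K", "sd",
                   "time_convention", "seed", "n_runs", "n_successes",
                   "t_max", "horizon", "t_grid_max", "source", "correction",
                   "record", "stop_at", "offspring", "establish_threshold",
                   "smooth", "out")

#' Read and validate a YAML run configuration
#'
#' Accepts every [rescue_params()] field plus run options (`seed`, `n_runs`,
#' `n_successes`, `t_max`, `horizon`, `t_grid_max`, `source`, `correction`,
#' `record`, `stop_at`, `offspring`, `establish_threshold`, `smooth`,
#' `out`). Unknown keys are rejected so typos fail loudly.
#'
#' @param path YAML file.
#' @return A list with element `params` (a [rescue_params()]) and the run
#'   options.
#' @export
read_rescue_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), config_fields)
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  pf <- intersect(names(cfg), c("N0", "r", "s", "u", "k", "p0", "K", "sd",
                                "time_convention"))
  params <- do.call(rescue_params, cfg[pf])
  c(list(params = params), cfg[setdiff(names(cfg), pf)])
}

#' Write a run configuration to YAML
#'
#' @param params A [rescue_params()] object.
#' @param path Output file.
#' @param ... Extra run options (validated against the known keys).
#' @return `path`, invisibly.
#' @export
write_rescue_config <- function(params, path, ...) {
  params <- as_rescue_params(params)
  extra <- list(...)
  unknown <- setdiff(names(extra), config_fields)
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- c(params[!vapply(params, is.null, logical(1))], extra)
  cfg$k <- NULL  # p0 and N0 determine k; keep the file minimal
  yaml::write_yaml(cfg, path)
  invisible(path)
}
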