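## Flat key=value configuration resolution for the command-line front end:
## defaults <- config file <- command-line flags, in that precedence.

scoring_defaults <- function() {
  list(w_base = 0.7, lambda_dfs = 0.2, decay_base = 0.9, bonus_cap = 1.8,
       isi_floor = 0.01, max_hops = 4, bonus_structural = 1.2,
       bonus_evidence = 1.5, other_gene_gene_weight = 0.9,
       specific_ingredient_threshold = 0.5, seed = 42, top_k = 10)
}

parse_kv_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  out <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "=", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      config_error(sprintf("malformed config line %d: %s", i, lines[i]))
    out[[trimws(parts[1])]] <- trimws(parts[2])
  }
  out
}

coerce_like <- function(value, template, key) {
  if (is.numeric(template)) {
    v <- suppressWarnings(as.numeric(value))
    if (is.na(v) && !is.na(value))
      config_error(sprintf("field %s expects a number, got '%s'", key, value))
    v
  } else as.character(value)
}

#' Resolve a run configuration
#'
#' Merges, in increasing precedence: documented defaults, a flat key=value
#' config file, and command-line style flags. Unknown keys are rejected
#' with the list of valid keys; values are coerced to the default's type.
#' A provenance stamp (config hash of the resolved values, seed) is
#' attached.
#'
#' @param file Optional path to a key=value config file.
#' @param flags Named list or character vector of overrides.
#' @param defaults Named list of defaults (scoring defaults if omitted).
#' @return Named list of resolved values with attributes `hash` and `seed`.
#' @export
kg_config <- function(file = NULL, flags = list(),
                      defaults = scoring_defaults()) {
  resolved <- defaults
  layers <- list()
  if (!is.null(file)) {
    if (!file.exists(file)) config_error(sprintf("no such config file: %s", file))
    layers <- c(layers, list(parse_kv_file(file)))
  }
  layers <- c(layers, list(as.list(flags)))
  for (layer in layers) {
    unknown <- setdiff(names(layer), names(defaults))
    if (length(unknown) > 0L)
      config_error(sprintf("unknown config key(s): %s (valid: %s)",
                           paste(unknown, collapse = ", "),
                           paste(names(defaults), collapse = ", ")))
    for (k in names(layer))
      resolved[[k]] <- coerce_like(layer[[k]], defaults[[k]], k)
  }
  stamp <- paste(names(resolved),
                 vapply(resolved, function(v) paste(format(v), collapse = ","),
                        character(1)),
                 sep = "=", collapse = ";")
  attr(resolved, "hash") <- sprintf("%08x", sum(utf8ToInt(stamp) *
                                                  seq_along(utf8ToInt(stamp))) %%
                                      .Machine$integer.max)
  attr(resolved, "seed") <- resolved$seed
  resolved
}

write_resolved_config <- function(config, dir) {
  lines <- c(paste0("# config_hash=", attr(config, "hash")),
             paste(names(config),
                   vapply(config, function(v) paste(format(v), collapse = ","),
                          character(1)), sep = "="))
  writeLines(lines, file.path(dir, "config.txt"))
}
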