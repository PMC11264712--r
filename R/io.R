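# Configuration files, run manifests and reproducibility plumbing.

#' Read and write design configuration files
#'
#' Design parameters and the prior are exchanged as a flat key-value YAML
#' file using the field names of [vb_params()] and [vb_prior()] (all
#' monetary amounts plain numbers in GBP). Keys `mu0`, `sigma_x` and `n0`
#' populate the prior; everything else populates the design parameters.
#' `sigma_x`, `tau` and `t_max` have no silent defaults: they must be
#' present in the file.
#'
#' @param path File path of the YAML configuration.
#' @param params A [vb_params()] object.
#' @param prior A [vb_prior()] object.
#' @return `vb_read_config()` returns a list with elements `params` and
#'   `prior`; `vb_write_config()` returns `path` invisibly.
#' @export
vb_read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("sigma_x", "tau", "t_max")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("configuration must specify: ", paste(miss, collapse = ", "),
         call. = FALSE)
  prior_keys <- intersect(c("mu0", "sigma_x", "n0"), names(cfg))
  prior <- do.call(vb_prior, cfg[prior_keys])
  par_keys <- setdiff(names(cfg), prior_keys)
  unknown <- setdiff(par_keys, names(formals(vb_params)))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  params <- do.call(vb_params, cfg[par_keys])
  list(params = params, prior = prior)
}

#' @rdname vb_read_config
#' @export
vb_write_config <- function(params, prior, path) {
  cfg <- c(unclass(params),
           list(mu0 = prior$mu0, sigma_x = prior$sigma_x, n0 = prior$n0))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Hash a configuration object
#'
#' Short stable FNV-1a hash of a configuration's deparsed contents, used
#' to tie output files to the settings that produced them.
#'
#' @param x Any R object.
#' @return Eight-character hexadecimal string.
#' @export
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  bytes <- utf8ToInt(s)
  # 31-bit polynomial rolling hash (double arithmetic stays exact)
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run manifest for a batch computation
#'
#' Records what was run: the command label, the configuration hash, the
#' seed, the package version, a timestamp and the output files, so any
#' stochastic batch output is traceable and exactly reproducible from its
#' manifest.
#'
#' @param command Character label of the computation.
#' @param config The configuration object (hashed into the manifest).
#' @param seed Integer seed used for the run.
#' @param outputs Character vector of output file paths.
#' @param path Optional path to write the manifest as JSON.
#' @return The manifest list, invisibly if written to file.
#' @export
vb_manifest <- function(command, config = NULL, seed = NULL,
                        outputs = character(0), path = NULL) {
  man <- list(command = command,
              config_hash = if (is.null(config)) NA_character_ else config_hash(config),
              seed = seed,
              package_version = as.character(utils::packageVersion("vbseq")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              outputs = outputs)
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, null = "null")
    return(invisible(man))
  }
  man
}
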