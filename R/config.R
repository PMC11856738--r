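# YAML round-trip for the network and training configurations, so runs can
# be described by a single config file (used by the command-line wrapper).

#' Write a combined network/training configuration to YAML
#'
#' @param net_cfg A [mcm_unet_config()].
#' @param train_cfg A [train_config()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(net_cfg, train_cfg, path) {
  yaml::write_yaml(list(network = unclass(net_cfg),
                        training = unclass(train_cfg)), path)
  invisible(path)
}

#' Read a combined configuration from YAML
#'
#' Missing fields take the package defaults.
#'
#' @param path YAML file written by [write_config()] (or hand-edited).
#' @return `list(network = mcm_unet_config, training = train_config)`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  net <- do.call(mcm_unet_config, raw$network %||% list())
  tr <- do.call(train_config, raw$training %||% list())
  list(network = net, training = tr)
}
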