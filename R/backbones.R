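#' Registry of pre-trained backbone networks
#'
#' The toolkit taps the layer feeding the final classification (softmax)
#' output of 16 pre-trained convolutional networks. The registry pins, for
#' each backbone, the expected input size and the length of that penultimate
#' activation vector. The pinned dimensions are authoritative: an extraction
#' backend that yields a different length for a registered name is rejected.
#'
#' @format A list of `backbone_spec` objects keyed by backbone name. Each
#'   spec has fields `name`, `input_size` (H, W in pixels), `layer_tag`
#'   (identifier of the tapped activation) and `feature_dim`.
#' @name backbone-registry
NULL

# name, input H/W, tapped layer, penultimate feature length
.BACKBONES <- list(
  list("DarkNet-19",          256, "global_avgpool",  1000),
  list("DarkNet-53",          256, "global_avgpool",  1024),
  list("DenseNet-201",        224, "global_avgpool",  1920),
  list("EfficientNet-b0",     224, "global_avgpool",  1280),
  list("GoogLeNet365",        224, "global_avgpool",  1024),
  list("GoogLeNet",           224, "global_avgpool",  1024),
  list("Inception-ResNet-v2", 299, "global_avgpool",  1536),
  list("Inception-v3",        299, "global_avgpool",  2048),
  list("MobileNet-v2",        224, "global_avgpool",  1280),
  list("NASNet-Mobile",       224, "global_avgpool",  1056),
  list("ResNet-101",          224, "global_avgpool",  2048),
  list("ResNet-50",           224, "global_avgpool",  2048),
  list("ResNet-18",           224, "global_avgpool",   512),
  list("ShuffleNet",          224, "global_avgpool",   544),
  list("SqueezeNet",          227, "global_avgpool",  1000),
  list("Xception",            299, "global_avgpool",  2048)
)

new_backbone_spec <- function(name, input_size, layer_tag, feature_dim) {
  stopifnot(is.character(name), length(name) == 1L, feature_dim > 0)
  structure(
    list(name = name, input_size = c(input_size, input_size),
         layer_tag = layer_tag, feature_dim = as.integer(feature_dim)),
    class = "backbone_spec"
  )
}

#' @export
print.backbone_spec <- function(x, ...) {
  cat(sprintf("<backbone_spec> %s: input %dx%d, layer '%s', %d features\n",
              x$name, x$input_size[1], x$input_size[2], x$layer_tag,
              x$feature_dim))
  invisible(x)
}

#' List the registered pre-trained backbones
#'
#' @return A named list of 16 `backbone_spec` objects (see
#'   [backbone-registry]).
#' @examples
#' names(list_backbones())
#' list_backbones()[["ResNet-50"]]$feature_dim  # 2048
#' @export
list_backbones <- function() {
  specs <- lapply(.BACKBONES, function(b) new_backbone_spec(b[[1]], b[[2]], b[[3]], b[[4]]))
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

#' Look up one backbone by name
#'
#' @param name backbone name as listed by [list_backbones()].
#' @return A `backbone_spec`.
#' @export
backbone_spec <- function(name) {
  reg <- list_backbones()
  if (!name %in% names(reg)) {
    stop(sprintf("unknown backbone '%s'; registered backbones: %s",
                 name, paste(names(reg), collapse = ", ")), call. = FALSE)
  }
  reg[[name]]
}
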