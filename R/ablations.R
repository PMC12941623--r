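## Config-driven construction of the ablation/benchmark variants on the
## shared backbone.

.variantNames <- function() {
  c("no_spatial_attention", "no_cfb", "swa1_standard_attention",
    "swa2_conv_aggregator", "swa3_convlstm", "no_dynnet", "no_pretrain",
    "no_augmentation")
}

#' List the ablation and benchmark variants
#'
#' @return data.frame with \code{name}, \code{level} ("model" or
#'   "training") and \code{description} for the eight variants; together
#'   with the reference they span the nine pairwise comparisons.
#' @export
listVariants <- function() {
  data.frame(
    name = .variantNames(),
    level = c("model", "model", "model", "model", "model", "model",
              "training", "training"),
    description = c(
      "Removes all spatial self-attention layers from the encoder and DynNet",
      "Replaces channel-fusion bottlenecks with simple residual skips",
      "Standard causal axial attention: three unshared temporal cores with causal time masking",
      "Replaces the temporal core with a convolutional aggregator (3-frame feature concatenation) at every level",
      "Replaces the attention core at L4/L5 with two stacked ConvLSTM cells; keeps spatial attention and CFB",
      "Removes the dynamics network and the reconstruction objective; decodes directly from the estimated state",
      "Skips the synthetic pretraining stage",
      "Disables online geometric and FAF-intensity augmentation"))
}

#' Build a model or training variant
#'
#' Model-level variants rebuild the backbone with the structural change;
#' training-level variants leave the model untouched and adjust the
#' training configuration (no pretraining stage / no online augmentation).
#' Every variant accepts the same 3-visit input and emits the same output
#' shapes as the reference.
#'
#' @param name one of \code{\link{listVariants}()$name}, or "reference".
#' @param baseConfig the reference \code{\link{modelConfig}} the variant is
#'   derived from.
#' @param trainCfg base \code{\link{trainConfig}}.
#' @param lossCfg base \code{\link{lossConfig}}.
#' @param seed weight-initialization seed.
#' @return List with \code{name}, \code{model}, \code{trainCfg},
#'   \code{lossCfg} ready for \code{\link{runTraining}}.
#' @export
buildVariant <- function(name, baseConfig = modelConfig(),
                         trainCfg = trainConfig(), lossCfg = lossConfig(),
                         seed = 1L) {
  ok <- c("reference", .variantNames())
  if (!name %in% ok)
    stop("configuration error: unknown variant '", name, "'; valid names: ",
         paste(ok, collapse = ", "))
  cfg <- baseConfig
  if (name %in% c("reference", "no_pretrain", "no_augmentation")) {
    cfg@variant <- "reference"
  } else {
    cfg@variant <- name
  }
  if (name == "no_pretrain") trainCfg@pretrainEpochs <- 0L
  if (name == "no_augmentation") {
    trainCfg@augmentGeometric <- FALSE
    trainCfg@augmentIntensity <- FALSE
  }
  if (name == "no_dynnet") lossCfg@lambdaRecon <- 0
  list(name = name, model = buildModel(cfg, seed = seed), trainCfg = trainCfg,
       lossCfg = lossCfg)
}
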