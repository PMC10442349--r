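# Backbone factory.  Ten standard architecture families are available by
# name as compact in-package presets (residual, inception-style,
# compound-scaled convolutional, and vision-transformer feature
# extractors), sized for CPU-scale experiments rather than as faithful
# ImageNet-scale replicas; `tiny_cnn` is the small three-block convnet used
# for desk-scale training runs.  Every backbone maps a standardized
# (H, W, 3, N) batch to an (N, feature_dim) feature matrix.

BACKBONE_NAMES <- c(
  "tiny_cnn", "resnet101", "inception_v3",
  paste0("efficientnet_b", 0:5), "vit_b16", "vit_b32"
)

# conv + relu
conv_block <- function(in_ch, out_ch, kernel = 3L, stride = 1L, pad = 1L) {
  nn_seq(nn_conv2d(in_ch, out_ch, kernel, stride, pad), nn_relu())
}

backbone_tiny_cnn <- function(width = 16L) {
  w <- as.integer(width)
  list(
    net = nn_seq(
      conv_block(3L, w, kernel = 5L, stride = 4L, pad = 2L),
      conv_block(w, 2L * w, stride = 2L),
      conv_block(2L * w, 4L * w, stride = 2L),
      nn_global_avg_pool()
    ),
    feature_dim = 4L * w
  )
}

res_stage <- function(in_ch, out_ch, n_blocks, stride) {
  blocks <- list(nn_residual(
    nn_seq(nn_conv2d(in_ch, out_ch, 3L, stride, 1L), nn_relu(), nn_conv2d(out_ch, out_ch, 3L, 1L, 1L)),
    shortcut = nn_conv2d(in_ch, out_ch, 1L, stride, 0L)
  ))
  for (i in seq_len(n_blocks - 1L)) {
    blocks[[length(blocks) + 1L]] <- nn_residual(
      nn_seq(nn_conv2d(out_ch, out_ch, 3L, 1L, 1L), nn_relu(), nn_conv2d(out_ch, out_ch, 3L, 1L, 1L))
    )
  }
  do.call(nn_seq, blocks)
}

# Residual preset with the ResNet-101 stage layout (3, 4, 23, 3), narrow.
backbone_resnet101 <- function(width = 8L) {
  w <- as.integer(width)
  list(
    net = nn_seq(
      conv_block(3L, w, kernel = 7L, stride = 2L, pad = 3L),
      nn_avg_pool(2L),
      res_stage(w, w, 3L, 1L),
      res_stage(w, 2L * w, 4L, 2L),
      res_stage(2L * w, 4L * w, 23L, 2L),
      res_stage(4L * w, 8L * w, 3L, 2L),
      nn_global_avg_pool()
    ),
    feature_dim = 8L * w
  )
}

inception_block <- function(in_ch, w) {
  nn_inception(list(
    conv_block(in_ch, w, kernel = 1L, pad = 0L),
    nn_seq(conv_block(in_ch, w, kernel = 1L, pad = 0L), conv_block(w, w)),
    nn_seq(conv_block(in_ch, w, kernel = 1L, pad = 0L), conv_block(w, w), conv_block(w, w)),
    nn_seq(nn_avg_pool(1L), conv_block(in_ch, w, kernel = 1L, pad = 0L))
  ))
}

backbone_inception_v3 <- function(width = 8L) {
  w <- as.integer(width)
  list(
    net = nn_seq(
      conv_block(3L, w, stride = 2L),
      conv_block(w, 2L * w, stride = 2L),
      inception_block(2L * w, w),
      nn_avg_pool(2L),
      inception_block(4L * w, 2L * w),
      nn_avg_pool(2L),
      inception_block(8L * w, 2L * w),
      nn_global_avg_pool()
    ),
    feature_dim = 8L * w
  )
}

# Compound-scaled convolutional preset: depth ~ 1.2^phi, width ~ 1.1^phi,
# the canonical EfficientNet scaling coefficients.
backbone_efficientnet <- function(phi, base_width = 8L) {
  d_mult <- 1.2^phi
  w_mult <- 1.1^phi
  depth <- function(d) as.integer(ceiling(d * d_mult))
  width <- function(w) as.integer(round(w * w_mult))
  stage <- function(in_ch, out_ch, n, stride) {
    blocks <- list(conv_block(in_ch, out_ch, stride = stride))
    for (i in seq_len(n - 1L)) {
      blocks[[length(blocks) + 1L]] <- nn_residual(
        nn_seq(nn_conv2d(out_ch, out_ch, 3L, 1L, 1L), nn_relu(), nn_conv2d(out_ch, out_ch, 3L, 1L, 1L))
      )
    }
    do.call(nn_seq, blocks)
  }
  w1 <- width(base_width); w2 <- width(2L * base_width); w3 <- width(4L * base_width)
  list(
    net = nn_seq(
      conv_block(3L, w1, stride = 2L),
      stage(w1, w1, depth(1L), 1L),
      stage(w1, w2, depth(2L), 2L),
      stage(w2, w3, depth(2L), 2L),
      nn_global_avg_pool()
    ),
    feature_dim = w3
  )
}

backbone_vit <- function(patch, img_size, dim = 64L, depth = 4L, n_heads = 4L) {
  layers <- list(nn_patch_embed(3L, dim, patch, img_size))
  for (i in seq_len(depth)) {
    layers[[length(layers) + 1L]] <- nn_transformer_block(dim, n_heads)
  }
  layers[[length(layers) + 1L]] <- nn_layer_norm(dim)
  layers[[length(layers) + 1L]] <- nn_token_mean()
  list(net = do.call(nn_seq, layers), feature_dim = dim)
}

#' Construct a backbone feature extractor by name
#'
#' @param name One of `r paste0('\x60', BACKBONE_NAMES, '\x60', collapse = ", ")`.
#' @param img_size Input patch side in pixels (needed by the
#'   vision-transformer presets for their positional embeddings).
#' @return List with `net` (the feature extractor) and `feature_dim`.
#' @keywords internal
build_backbone <- function(name, img_size = 64L) {
  if (!name %in% BACKBONE_NAMES) {
    hx_validation_error(
      "unknown backbone '", name, "'; supported: ",
      paste(BACKBONE_NAMES, collapse = ", ")
    )
  }
  switch(name,
    tiny_cnn = backbone_tiny_cnn(),
    resnet101 = backbone_resnet101(),
    inception_v3 = backbone_inception_v3(),
    vit_b16 = backbone_vit(16L, img_size),
    vit_b32 = backbone_vit(32L, img_size),
    backbone_efficientnet(as.integer(sub("efficientnet_b", "", name)))
  )
}
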