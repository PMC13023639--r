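# Full segmentation model: a single-channel pyramid-transformer backbone with
# spatial-reduction attention (SRA), the radial intensity module on low-level
# features, deformable cross-scale fusion, boundary-aware attention and a
# single-channel segmentation head. Module flags reproduce the ablation
# variants (w/o RIM, w/o D-CFM, w/o BAM).

#' Model configuration
#'
#' @param input_channels must be 1 (single-channel stem)
#' @param widths channel widths of the four pyramid stages
#' @param depths transformer blocks per stage
#' @param sra_ratios key/value spatial-reduction ratios per stage
#' @param mlp_ratio hidden expansion of the transformer MLPs
#' @param decoder_channels common decoder width
#' @param rim,dcfm,bam module flags (ablation switches)
#' @param rim_n_theta,rim_n_r,rim_kernel_theta,rim_dct_k RIM settings
#' @param rim_center_mode lumen-centre estimator for the polar grid
#' @param bam_window,bam_sigma,bam_tau_mode,bam_heads BAM settings
#' @param mid_level which stage feeds the mid-level branch (`"f2"` or `"f3"`)
#' @return named list of class `model_config`
#' @export
model_config <- function(input_channels = 1L,
                         widths = c(32L, 64L, 160L, 256L),
                         depths = c(1L, 1L, 1L, 1L),
                         sra_ratios = c(8L, 4L, 2L, 1L),
                         mlp_ratio = 2L,
                         decoder_channels = 32L,
                         rim = TRUE, dcfm = TRUE, bam = TRUE,
                         rim_n_theta = 720L, rim_n_r = NULL,
                         rim_kernel_theta = 7L, rim_dct_k = 16L,
                         rim_center_mode = "image_center",
                         bam_window = 7L, bam_sigma = 1.0,
                         bam_tau_mode = "quantile", bam_heads = 1L,
                         mid_level = c("f2", "f3")) {
  mid_level <- match.arg(mid_level)
  if (input_channels != 1L)
    stop("model_config: the input stem is single-channel (input_channels = 1)")
  stopifnot(length(widths) == 4L, length(depths) == 4L, length(sra_ratios) == 4L)
  structure(list(input_channels = 1L, widths = as.integer(widths),
                 depths = as.integer(depths), sra_ratios = as.integer(sra_ratios),
                 mlp_ratio = as.integer(mlp_ratio),
                 decoder_channels = as.integer(decoder_channels),
                 rim = rim, dcfm = dcfm, bam = bam,
                 rim_n_theta = as.integer(rim_n_theta), rim_n_r = rim_n_r,
                 rim_kernel_theta = as.integer(rim_kernel_theta),
                 rim_dct_k = as.integer(rim_dct_k),
                 rim_center_mode = rim_center_mode,
                 bam_window = as.integer(bam_window), bam_sigma = bam_sigma,
                 bam_tau_mode = bam_tau_mode, bam_heads = as.integer(bam_heads),
                 mid_level = mid_level),
            class = "model_config")
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

stage_new <- function(cin, cout, k, stride, depth, ratio, mlp_ratio) {
  st <- list(patch = nn_conv2d(cin, cout, k = k, stride = stride),
             lnp = nn_layernorm(cout),
             blocks = lapply(seq_len(depth), function(i) {
               list(ln1 = nn_layernorm(cout),
                    wq = nn_linear(cout, cout), wk = nn_linear(cout, cout),
                    wv = nn_linear(cout, cout), wo = nn_linear(cout, cout),
                    ln2 = nn_layernorm(cout),
                    m1 = nn_linear(cout, cout * mlp_ratio),
                    m2 = nn_linear(cout * mlp_ratio, cout))
             }),
             cout = cout, ratio = ratio)
  st$fwd <- function(x) {
    x <- st$patch$fwd(x)
    dm <- dim(val(x)); H <- dm[1]; W <- dm[2]; C <- dm[3]
    r <- gcd2(st$ratio, gcd2(H, W))
    t <- st$lnp$fwd(ad_reshape(x, c(H * W, C)))
    for (b in st$blocks) {
      tl <- b$ln1$fwd(t)
      q <- b$wq$fwd(tl)
      kvmap <- ad_avgpool(ad_reshape(tl, c(H, W, C)), r)
      kvt <- ad_reshape(kvmap, c((H %/% r) * (W %/% r), C))
      kk <- b$wk$fwd(kvt); vv <- b$wv$fwd(kvt)
      A <- ad_softmax_rows(ad_cmul(ad_matmul(q, kk, tb = TRUE), 1 / sqrt(C)))
      t <- ad_add(t, b$wo$fwd(ad_matmul(A, vv)))
      tl2 <- b$ln2$fwd(t)
      t <- ad_add(t, b$m2$fwd(ad_relu(b$m1$fwd(tl2))))
    }
    ad_reshape(t, c(H, W, C))
  }
  st
}

#' Build the segmentation model
#'
#' @param config a [model_config()]
#' @param seed integer seed for weight initialisation
#' @return model object (nested module list) with forward closures
#' @export
build_model <- function(config = model_config(), seed = 0L) {
  with_seed(seed, {
    w <- config$widths
    Cd <- config$decoder_channels
    model <- list(
      config = config,
      stages = list(
        stage_new(config$input_channels, w[1], 7L, 4L, config$depths[1],
                  config$sra_ratios[1], config$mlp_ratio),
        stage_new(w[1], w[2], 3L, 2L, config$depths[2], config$sra_ratios[2],
                  config$mlp_ratio),
        stage_new(w[2], w[3], 3L, 2L, config$depths[3], config$sra_ratios[3],
                  config$mlp_ratio),
        stage_new(w[3], w[4], 3L, 2L, config$depths[4], config$sra_ratios[4],
                  config$mlp_ratio)),
      rim = if (config$rim)
        rim_new(w[1], rim_params(config$rim_kernel_theta, config$rim_dct_k),
                n_theta = config$rim_n_theta, n_r = config$rim_n_r,
                center_mode = config$rim_center_mode) else NULL,
      proj_l = nn_conv2d(w[1], Cd, k = 1L, pad = 0L),
      proj_m = list(nn_conv2d(w[2], Cd, k = 1L, pad = 0L),
                    nn_conv2d(w[3], Cd, k = 1L, pad = 0L),
                    nn_conv2d(w[4], Cd, k = 1L, pad = 0L)),
      dcfm = if (config$dcfm) dcfm_new(Cd, Cd, Cd, gate = TRUE) else NULL,
      fuse_plain = if (!config$dcfm) list(conv = nn_conv2d(Cd, Cd, k = 3L),
                                          proj = nn_conv2d(Cd, Cd, k = 1L, pad = 0L))
                   else NULL,
      bam = if (config$bam) bam_new(Cd, window = config$bam_window,
                                    heads = config$bam_heads) else NULL,
      ln_out = nn_layernorm(Cd),
      aux_head = nn_conv2d(Cd, 1L, k = 1L, pad = 0L, bias_init = 0),
      up1 = nn_conv2d(Cd, Cd %/% 2L, k = 3L),
      img_stem = nn_conv2d(1L, Cd %/% 4L, k = 3L, zero_init = TRUE),
      up2 = nn_conv2d(Cd %/% 2L + Cd %/% 4L, Cd %/% 4L, k = 3L),
      head = nn_conv2d(Cd %/% 4L, 1L, k = 1L, pad = 0L, bias_init = 0))
    model
  })
}

check_input_image <- function(image) {
  d <- dim(image)
  if (length(d) == 3L && d[3] == 3L)
    stop("single-channel contract: got a 3-channel input; convert to grayscale first")
  if (length(d) == 3L && d[3] != 1L)
    stop("input must be a single-channel image")
  invisible(image)
}

pad_input_32 <- function(image) {
  d <- dim(image)
  H <- d[1]; W <- d[2]
  Hp <- ceiling(H / 32) * 32; Wp <- ceiling(W / 32) * 32
  x <- array(image, c(H, W, 1L))
  node <- ad_const(x)
  if (Hp > H || Wp > W) node <- ad_pad(node, 0L, Hp - H, 0L, Wp - W, "reflect")
  list(node = node, H = H, W = W, Hp = Hp, Wp = Wp)
}

#' Run the pyramid backbone
#'
#' @param model a [build_model()] model
#' @param image grayscale matrix in `[0, 1]` (or `(H, W, 1)` array);
#'   three-channel inputs are rejected
#' @return list of four feature maps at strides 4, 8, 16, 32 (arrays)
#' @export
backbone_forward <- function(model, image) {
  check_input_image(image)
  pi <- pad_input_32(if (length(dim(image)) == 3L) image[, , 1L] else image)
  x <- pi$node
  out <- list()
  for (s in model$stages) { x <- s$fwd(x); out[[length(out) + 1L]] <- x }
  lapply(out, val)
}

model_forward_node <- function(model, image) {
  check_input_image(image)
  img <- if (length(dim(image)) == 3L) image[, , 1L] else image
  pi <- pad_input_32(img)
  cfg <- model$config
  x <- pi$node
  feats <- list()
  for (s in model$stages) { x <- s$fwd(x); feats[[length(feats) + 1L]] <- x }
  f1 <- feats[[1]]
  if (cfg$rim) f1 <- model$rim$fwd(f1, image = img)
  fl <- ad_relu(model$proj_l$fwd(f1))
  ms <- lapply(1:3, function(i) ad_relu(model$proj_m[[i]]$fwd(feats[[i + 1L]])))
  base <- if (cfg$mid_level == "f2") 1L else 2L
  bd <- dim(val(ms[[base]]))
  fm <- ms[[base]]
  for (i in setdiff(1:3, base)) {
    mi <- ms[[i]]
    di <- dim(val(mi))
    if (di[1] != bd[1] || di[2] != bd[2]) mi <- ad_upsample_bilinear(mi, bd[1], bd[2])
    fm <- ad_add(fm, mi)
  }
  ld <- dim(val(fl))
  fused <- if (cfg$dcfm) {
    model$dcfm$fwd(fl, fm)
  } else {
    up <- ad_upsample_bilinear(fm, ld[1], ld[2])
    ad_add(model$fuse_plain$conv$fwd(fl), model$fuse_plain$proj$fwd(up))
  }
  fused <- ad_relu(fused)
  if (cfg$bam)
    fused <- bam_forward(fused, model$bam, sigma = cfg$bam_sigma,
                         tau_mode = cfg$bam_tau_mode)
  fd <- dim(val(fused))
  fused <- ad_reshape(model$ln_out$fwd(ad_reshape(fused, c(fd[1] * fd[2], fd[3]))), fd)
  # auxiliary deeply-supervised head on the fused stride-4 map
  aux <- ad_sigmoid(ad_upsample_bilinear(model$aux_head$fwd(fused), pi$Hp, pi$Wp))
  if (pi$Hp > pi$H || pi$Wp > pi$W) aux <- ad_crop(aux, 1L, pi$H, 1L, pi$W)
  # progressive upsampling head: refine boundaries at stride 2 then stride 1
  x <- ad_relu(model$up1$fwd(ad_upsample_bilinear(fused, fd[1] * 2L, fd[2] * 2L)))
  skip <- ad_relu(model$img_stem$fwd(pi$node))   # full-resolution intensity skip
  x <- ad_relu(model$up2$fwd(ad_concat_ch(ad_upsample_bilinear(x, pi$Hp, pi$Wp), skip)))
  logits <- model$head$fwd(x)
  if (pi$Hp > pi$H || pi$Wp > pi$W) logits <- ad_crop(logits, 1L, pi$H, 1L, pi$W)
  main <- ad_sigmoid(logits)
  attr(main, "aux") <- aux
  main
}

#' Full forward pass to a lumen probability map
#'
#' @param model a [build_model()] model
#' @param image grayscale matrix in `[0, 1]`
#' @return `(H, W)` matrix of per-pixel lumen probabilities in `(0, 1)`
#' @export
model_forward <- function(model, image) {
  p <- val(model_forward_node(model, image))
  matrix(p, dim(p)[1], dim(p)[2])
}

#' Save model weights and configuration to a single-file checkpoint
#' @param model model object
#' @param path output file
#' @param extra optional named list stored alongside (e.g. training metadata)
#' @export
save_checkpoint <- function(model, path, extra = list()) {
  saveRDS(list(config = model$config, state = get_state(model), extra = extra), path)
  invisible(path)
}

#' Load a checkpoint written by [save_checkpoint()]
#' @param path checkpoint file
#' @return list with `model` (weights restored) and `extra`
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(do.call(model_config, ck$config[setdiff(names(ck$config), NULL)]))
  set_state(model, ck$state)
  list(model = model, config = ck$config, extra = ck$extra)
}
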