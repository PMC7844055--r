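#' Save and load a fitted decoder as a single JSON document
#'
#' The whole model - control parameters, seeds, template, montage, sparse
#' reservoir weights, codec thresholds, populations with member weights and
#' afferent index sets - is written to one JSON file at full numeric
#' precision, so a reloaded model reproduces every prediction of the
#' original exactly and two identical fits serialise to byte-identical
#' files.
#'
#' @param model a fitted [snn_decoder()].
#' @param path output file path.
#' @return `save_decoder()` returns `path` invisibly; `load_decoder()`
#'   returns the reconstructed `snn_decoder`.
#' @export
save_decoder <- function(model, path) {
  stopifnot(inherits(model, "snn_decoder"))
  w <- model$reservoir$weights
  mask <- model$reservoir$mask
  idx <- which(mask, arr.ind = TRUE)
  tpl <- model$reservoir$template
  doc <- list(
    format = "snndecoder-model-1",
    seed = model$seed,
    sample_rate = model$sample_rate,
    n_training_trials = model$n_training_trials,
    control = unclass(model$control),
    template = list(
      x = tpl$x, y = tpl$y, z = tpl$z, region = tpl$region,
      semi_axes = attr(tpl, "semi_axes"),
      resolution = attr(tpl, "resolution"),
      shell_fraction = attr(tpl, "shell_fraction")
    ),
    montage = as.list(model$montage),
    input_map = as.list(model$input_map),
    lif = model$reservoir$lif,
    inhibitory = model$reservoir$inhibitory,
    synapses = list(pre = idx[, 1], post = idx[, 2], w = w[idx]),
    thresholds_in = list(channels = model$thresholds_in$channels,
                         sample_rate = model$thresholds_in$sample_rate),
    thresholds_tg = list(channels = model$thresholds_tg$channels,
                         sample_rate = model$thresholds_tg$sample_rate),
    target_labels = model$target_labels,
    target_kind = as.list(model$target_kind),
    sign_profiles = model$sign_profiles,
    populations = lapply(model$populations, function(p) list(
      label = p$label, th_n = p$th_n, next_cluster = p$next_cluster,
      current_scale = p$current_scale %||% 1,
      members = lapply(p$members, function(m) list(
        weights = m$weights, afferents = m$afferents, cluster = m$cluster,
        trained = m$trained, accuracy = m$accuracy,
        w_readout = m$w_readout))
    ))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE,
                       digits = I(17), pretty = FALSE)
  invisible(path)
}

#' @rdname save_decoder
#' @export
load_decoder <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (!identical(doc$format, "snndecoder-model-1"))
    stop("not a snndecoder model file", call. = FALSE)
  tpl <- structure(
    data.frame(x = unlist(doc$template$x), y = unlist(doc$template$y),
               z = unlist(doc$template$z),
               region = unlist(doc$template$region)),
    class = c("brain_template", "data.frame"),
    semi_axes = unlist(doc$template$semi_axes),
    resolution = doc$template$resolution,
    shell_fraction = doc$template$shell_fraction)
  n <- nrow(tpl)
  w <- matrix(0, n, n)
  mask <- matrix(FALSE, n, n)
  pre <- unlist(doc$synapses$pre); post <- unlist(doc$synapses$post)
  ij <- cbind(pre, post)
  mask[ij] <- TRUE
  w[ij] <- unlist(doc$synapses$w)
  lif <- doc$lif
  lif$w_clip <- unlist(lif$w_clip)
  input_map <- unlist(doc$input_map)
  reservoir <- structure(list(
    template = tpl, weights = w, mask = mask,
    inhibitory = unlist(doc$inhibitory), input_map = input_map,
    lif = lif), class = "snn_reservoir")
  rebuild_th <- function(x) structure(
    list(channels = lapply(x$channels, function(e)
      list(th = e$th, c = e$c, mean = e$mean, std = e$std,
           initial = e$initial)),
      sample_rate = x$sample_rate), class = "encoding_thresholds")
  populations <- lapply(doc$populations, function(p) structure(list(
    label = p$label, th_n = p$th_n, next_cluster = p$next_cluster,
    current_scale = p$current_scale,
    members = lapply(p$members, function(m) list(
      weights = unlist(m$weights), afferents = unlist(m$afferents),
      cluster = m$cluster, trained = m$trained,
      accuracy = m$accuracy %||% NA_real_, w_readout = m$w_readout))
  ), class = "span_population"))
  ctrl <- doc$control
  # vectors flattened by JSON back to the shapes snn_control expects
  ctrl$template$semi_axes <- unlist(ctrl$template$semi_axes)
  ctrl$reservoir$w_clip <- unlist(ctrl$reservoir$w_clip)
  class(ctrl) <- "snn_control"
  structure(list(
    reservoir = reservoir, clusters = extract_clusters(tpl),
    input_map = input_map,
    montage = data.frame(label = unlist(doc$montage$label),
                         x = unlist(doc$montage$x),
                         y = unlist(doc$montage$y),
                         z = unlist(doc$montage$z)),
    thresholds_in = rebuild_th(doc$thresholds_in),
    thresholds_tg = rebuild_th(doc$thresholds_tg),
    populations = populations,
    target_labels = unlist(doc$target_labels),
    target_kind = unlist(doc$target_kind),
    sign_profiles = lapply(doc$sign_profiles, unlist),
    sample_rate = doc$sample_rate,
    control = ctrl, seed = doc$seed,
    n_training_trials = doc$n_training_trials, call = NULL
  ), class = "snn_decoder")
}

#' Write prediction outputs as CSV files
#'
#' Writes `decoded.csv` (the decoded continuous targets),
#' `readout_spikes.csv` (population, time) and `member_spikes.csv`
#' (population, member, time) into a directory. Deterministic content for
#' deterministic predictions.
#'
#' @param prediction an `snn_prediction`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_prediction <- function(prediction, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_signal_csv(prediction$decoded, file.path(dir, "decoded.csv"))
  ro <- do.call(rbind, lapply(names(prediction$readout_spikes), function(lb) {
    tt <- prediction$readout_spikes[[lb]]
    if (!length(tt)) return(NULL)
    data.frame(population = lb, time = tt)
  }))
  if (is.null(ro)) ro <- data.frame(population = character(),
                                    time = numeric())
  utils::write.csv(ro, file.path(dir, "readout_spikes.csv"),
                   row.names = FALSE)
  ms <- do.call(rbind, lapply(names(prediction$member_spikes), function(lb) {
    do.call(rbind, lapply(seq_along(prediction$member_spikes[[lb]]),
                          function(i) {
      tt <- prediction$member_spikes[[lb]][[i]]
      if (!length(tt)) return(NULL)
      data.frame(population = lb, member = i, time = tt)
    }))
  }))
  if (is.null(ms)) ms <- data.frame(population = character(),
                                    member = integer(), time = numeric())
  utils::write.csv(ms, file.path(dir, "member_spikes.csv"),
                   row.names = FALSE)
  invisible(dir)
}
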