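# Corpus and image I/O: 8-bit grayscale PNG pairs with a manifest CSV,
# optional NIfTI export of stacked slices, and YAML run configuration.

#' Write a phantom corpus as PNG image/mask pairs with a manifest
#'
#' @param corpus list with `train` and `test` sample lists.
#' @param dir output directory (created if missing).
#' @param nifti logical; additionally write the stacked slices of each
#'   split as a NIfTI volume.
#' @return the manifest data frame, invisibly.
#' @export
write_corpus <- function(corpus, dir, nifti = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  for (split in names(corpus)) {
    for (s in corpus[[split]]) {
      img_path <- file.path(dir, paste0(s$id, "_image.png"))
      msk_path <- file.path(dir, paste0(s$id, "_mask.png"))
      png::writePNG(s$image / 255, img_path)
      png::writePNG(s$mask, msk_path)
      manifest[[length(manifest) + 1L]] <-
        data.frame(id = s$id, split = split, image = basename(img_path),
                   mask = basename(msk_path))
    }
    if (nifti && length(corpus[[split]])) {
      d <- dim(corpus[[split]][[1]]$image)
      vol <- array(0, c(d[1], d[2], length(corpus[[split]])))
      for (j in seq_along(corpus[[split]]))
        vol[, , j] <- corpus[[split]][[j]]$image
      RNifti::writeNifti(vol, file.path(dir, paste0(split, ".nii.gz")))
    }
  }
  manifest <- do.call(rbind, manifest)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Load a corpus written by [write_corpus()]
#'
#' @param dir corpus directory containing `manifest.csv`.
#' @return list of sample lists, one per split.
#' @export
load_corpus <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  out <- list()
  for (split in unique(manifest$split)) {
    rows <- manifest[manifest$split == split, ]
    out[[split]] <- lapply(seq_len(nrow(rows)), function(i) {
      img <- png::readPNG(file.path(dir, rows$image[i]))
      if (length(dim(img)) == 3L) img <- img[, , 1]
      msk <- png::readPNG(file.path(dir, rows$mask[i]))
      if (length(dim(msk)) == 3L) msk <- msk[, , 1]
      structure(list(image = img * 255, mask = (msk >= 0.5) * 1,
                     id = rows$id[i]), class = "slice_sample")
    })
  }
  out
}

#' Slice a NIfTI volume into preprocessed 2D samples
#'
#' Reads a volume, takes 2D slices along the chosen axis, min-max rescales
#' each to `[0, 255]` and resizes to `target_size`; an optional mask volume
#' is sliced with nearest-neighbour resampling and re-binarised.
#'
#' @param path NIfTI image file.
#' @param mask_path optional NIfTI label file with matching dimensions.
#' @param axis slicing axis (default 3, axial).
#' @param target_size output edge length (default 256).
#' @return list of `slice_sample`s (mask all-zero when no labels given).
#' @export
nifti_to_slices <- function(path, mask_path = NULL, axis = 3L,
                            target_size = 256L) {
  vol <- RNifti::asNifti(RNifti::readNifti(path))
  vol <- as.array(vol)
  msk <- if (!is.null(mask_path)) as.array(RNifti::readNifti(mask_path))
         else NULL
  n <- dim(vol)[axis]
  take <- function(v, i) {
    switch(axis, v[i, , ], v[, i, ], v[, , i])
  }
  lapply(seq_len(n), function(i) {
    sl <- take(vol, i)
    img <- if (diff(range(sl)) == 0) matrix(0, target_size, target_size)
           else preprocess_slice(sl, target_size)
    m <- if (is.null(msk)) matrix(0, target_size, target_size)
         else preprocess_mask(take(msk, i), target_size)
    structure(list(image = img, mask = m,
                   id = sprintf("%s_slice_%04d",
                                sub("\\.nii(\\.gz)?$", "", basename(path)),
                                i)),
              class = "slice_sample")
  })
}

#' Read a YAML run configuration
#'
#' Recognised subtrees: `model:` ([model_spec()] fields), `airseg:`
#' ([airseg_config()] fields, with `lem:` nested as [lem_config()] fields),
#' `train:` ([train_config()] fields) and `phantom:` ([phantom_spec()]
#' fields).
#'
#' @param path YAML file.
#' @return list with `model`, `train` and `phantom` objects.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  airseg <- NULL
  if (!is.null(y$airseg)) {
    a <- y$airseg
    if (!is.null(a$lem)) a$lem <- do.call(lem_config, a$lem)
    if (!is.null(a$stage_mask)) a$stage_mask <- unlist(a$stage_mask)
    airseg <- do.call(airseg_config, a)
  }
  model <- NULL
  if (!is.null(y$model)) {
    m <- y$model
    no_as <- isTRUE(m$no_airseg)
    m$no_airseg <- NULL
    if (!is.null(airseg)) m$airseg <- airseg
    if (no_as) m["airseg"] <- list(NULL)
    model <- do.call(model_spec, m)
  }
  tr <- if (!is.null(y$train)) do.call(train_config, y$train)
        else train_config()
  ph <- if (!is.null(y$phantom)) do.call(phantom_spec, y$phantom)
        else phantom_spec()
  list(model = model, train = tr, phantom = ph)
}
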