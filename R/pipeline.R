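# Processing-path enumeration and execution. A path is one
# (preprocess, operator, feature-or-parameter, postprocess) tuple; the
# default graph applies every preprocess and every postprocess to every
# real-valued operator, and preprocess only to label-valued operators
# (LBP, CLU, QNT), whose maps are rendered by plain normalization.

REAL_OPERATORS <- c("FOF", "GLCM", "GTDM", "RLM", "LAWS")
LABEL_OPERATORS <- c("LBP", "CLU", "QNT")

#' Registry of texture features
#'
#' One row per feature identifier: the six first-order features, fourteen
#' co-occurrence features, five gray-tone-difference features, eleven
#' run-length features, nine Laws energy maps, plus the parameterized
#' label operators (LBP radii, CLU/QNT cluster counts) for a given
#' configuration.
#'
#' @param config optional [pipeline_config()]; its grids determine the
#'   LBP/CLU/QNT rows. Defaults to the default configuration.
#' @return data.frame with columns `operator`, `feature`, `description`.
#' @export
feature_registry <- function(config = pipeline_config()) {
  fof_desc <- c("Mean", "Variance", "Skewness", "Kurtosis", "Energy", "Entropy")
  glcm_desc <- c("Angular second moment (energy)", "Contrast", "Correlation",
                 "Variance", "Inverse difference moment (homogeneity)",
                 "Sum average", "Sum variance", "Sum entropy", "Entropy",
                 "Difference variance", "Difference entropy",
                 "Information measure of correlation I",
                 "Information measure of correlation II",
                 "Maximal correlation coefficient")
  gtdm_desc <- c("Coarseness", "Contrast", "Busyness", "Complexity",
                 "Texture strength")
  rlm_desc <- c("Short run emphasis", "Long run emphasis",
                "Gray level nonuniformity", "Run-length nonuniformity",
                "Run percentage", "Low gray level run emphasis",
                "High gray level run emphasis",
                "Short run low gray level run emphasis",
                "Short run high gray level run emphasis",
                "Long run low gray level run emphasis",
                "Long run high gray level run emphasis")
  laws_names <- c("E5E5", "E5L5", "E5R5", "E5S5", "L5R5", "L5S5",
                  "R5R5", "R5S5", "S5S5")
  rbind(
    data.frame(operator = "FOF", feature = paste0("FOF-F", 1:6),
               description = fof_desc),
    data.frame(operator = "GLCM", feature = paste0("GLCM-F", 1:14),
               description = glcm_desc),
    data.frame(operator = "GTDM", feature = paste0("GTDM-F", 1:5),
               description = gtdm_desc),
    data.frame(operator = "RLM", feature = paste0("RLM-F", 1:11),
               description = rlm_desc),
    data.frame(operator = "LAWS", feature = paste0("LAWS-F", 1:9),
               description = paste("Texture energy,", laws_names, "masks")),
    data.frame(operator = "LBP",
               feature = sprintf("LBP-R%g", config$lbp_radii),
               description = sprintf("Local binary pattern code, P = 8, R = %g",
                                     config$lbp_radii)),
    data.frame(operator = "CLU", feature = sprintf("CLU-k%d", config$clu_k),
               description = sprintf("k-means intensity clustering, k = %d",
                                     config$clu_k)),
    data.frame(operator = "QNT", feature = sprintf("QNT-k%d", config$qnt_k),
               description = sprintf("Equal-spacing quantization, k = %d",
                                     config$qnt_k))
  )
}

#' Pipeline configuration
#'
#' Collects every tunable of the processing graph: moving-window side,
#' quantization levels, SDA parameters, operator grids (LBP radii and
#' cluster-count grids), the preprocessing and post-processing lists, and
#' the seed for the clustering stage. The configuration round-trips
#' through YAML unchanged ([config_write()] / [config_read()]).
#'
#' @param window_side odd moving-window side (default 21).
#' @param levels quantized gray levels for GLCM/RLM (default 32).
#' @param pre subset of `c("raw", "heq", "sda")`.
#' @param post subset of `c("none", "hstr", "heq")` for real-valued maps.
#' @param operators operator families to run.
#' @param lbp_radii LBP radius grid (default 5:20 at P = 8).
#' @param clu_k,qnt_k cluster-count grids (default 10, 20, 30, 40, 50).
#' @param sda_radius,sda_threshold SDA parameters (defaults 20 and 0).
#' @param glcm_d co-occurrence distance (default 1).
#' @param gtdm_K gray-tone-difference neighbourhood radius (default 1).
#' @param seed integer seed for the clustering stage.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(window_side = 21L, levels = 32L,
                            pre = c("raw", "heq", "sda"),
                            post = c("none", "hstr", "heq"),
                            operators = c(REAL_OPERATORS, LABEL_OPERATORS),
                            lbp_radii = 5:20,
                            clu_k = c(10L, 20L, 30L, 40L, 50L),
                            qnt_k = c(10L, 20L, 30L, 40L, 50L),
                            sda_radius = 20L, sda_threshold = 0L,
                            glcm_d = 1L, gtdm_K = 1L, seed = 1L) {
  pre <- match.arg(pre, c("raw", "heq", "sda"), several.ok = TRUE)
  post <- match.arg(post, c("none", "hstr", "heq"), several.ok = TRUE)
  operators <- match.arg(operators, c(REAL_OPERATORS, LABEL_OPERATORS),
                         several.ok = TRUE)
  if (length(operators) == 0L) stop("at least one operator is required")
  if (length(lbp_radii) == 0L || length(clu_k) == 0L || length(qnt_k) == 0L) {
    stop("operator parameter grids must be non-empty")
  }
  structure(list(window_side = as.integer(window_side),
                 levels = as.integer(levels),
                 pre = pre, post = post, operators = operators,
                 lbp_radii = as.numeric(lbp_radii),
                 clu_k = as.integer(clu_k), qnt_k = as.integer(qnt_k),
                 sda_radius = as.integer(sda_radius),
                 sda_threshold = as.integer(sda_threshold),
                 glcm_d = as.integer(glcm_d), gtdm_K = as.integer(gtdm_K),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
config_write <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
config_read <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(pipeline_config, x)
}

#' Enumerate all processing paths of a configuration
#'
#' Full factorial product of preprocessing x operator feature/parameter x
#' applicable post-processing, in a stable deterministic order
#' (operators in configuration order, features in registry order, then
#' preprocessing, then post-processing). Label-valued operators take only
#' the pass-through post step. The row count therefore equals
#' `sum over operators of |pre| * |features| * |applicable post|`.
#'
#' @param config a [pipeline_config()].
#' @return data.frame with columns `pre`, `operator`, `feature`, `post`
#'   and `path_id`.
#' @export
enumerate_paths <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  reg <- feature_registry(config)
  out <- list()
  for (op in config$operators) {
    feats <- reg$feature[reg$operator == op]
    posts <- if (op %in% LABEL_OPERATORS) "none" else config$post
    grid <- expand.grid(post = posts, pre = config$pre, feature = feats,
                        stringsAsFactors = FALSE)
    out[[op]] <- data.frame(pre = grid$pre, operator = op,
                            feature = grid$feature, post = grid$post)
  }
  paths <- do.call(rbind, out)
  rownames(paths) <- NULL
  paths$path_id <- sprintf("%s__%s-%s__%s", paths$pre, paths$operator,
                           sub("^[A-Z]+-", "", paths$feature), paths$post)
  paths
}

# Preprocess a radiograph to the 8-bit working image for a given entry
# transformation.
apply_preprocess <- function(image, pre, config) {
  switch(pre,
    raw = bit_reduce(image, 8L),
    heq = bit_reduce(histogram_equalize(image), 8L),
    sda = scale_sda_to_8bit(
      sda(image, sda_params(config$sda_radius, config$sda_threshold))),
    stop("unknown preprocess: ", pre))
}

# Compute every feature map of one operator family on a preprocessed
# image; returns a named list of feature_map objects.
compute_operator_maps <- function(image8, operator, config) {
  spec <- window_spec(config$window_side)
  switch(operator,
    FOF = fof_maps(image8, spec),
    GLCM = glcm_maps(image8, spec, levels = config$levels, d = config$glcm_d),
    GTDM = gtdm_maps(image8, spec, K = config$gtdm_K),
    RLM = rlm_maps(image8, spec, levels = config$levels),
    LAWS = laws_maps(image8, spec),
    LBP = {
      maps <- lapply(config$lbp_radii,
                     function(r) lbp_map(image8, lbp_params(8L, r)))
      names(maps) <- sprintf("LBP-R%g", config$lbp_radii)
      maps
    },
    CLU = {
      maps <- lapply(config$clu_k, function(k) {
        kmeans_intensity(image8, k, seed = config$seed, init = "random")$map
      })
      names(maps) <- sprintf("CLU-k%d", config$clu_k)
      maps
    },
    QNT = {
      maps <- lapply(config$qnt_k,
                     function(k) equal_spacing_quantize_map(image8, k))
      names(maps) <- sprintf("QNT-k%d", config$qnt_k)
      maps
    },
    stop("unknown operator: ", operator))
}

apply_postprocess <- function(map, post) {
  if (map$value_domain == "label" || post == "none") return(normalize_8bit(map))
  switch(post, hstr = hstr(map), heq = heq_post(map),
         stop("unknown postprocess: ", post))
}

#' Execute one processing path
#'
#' Runs preprocess, operator and post-processing for a single path row
#' (as produced by [enumerate_paths()]) and optionally writes the 8-bit
#' rendering (PNG) and the float map (TIFF) under
#' `{stem}__{pre}__{operator}-{feature}__{post}.{png,tiff}`.
#'
#' @param image input `radiograph`.
#' @param path one-row data.frame from [enumerate_paths()] (or a list with
#'   `pre`, `operator`, `feature`, `post`).
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @param stem file-name stem for outputs (default "image").
#' @param write_float also write the raw float map (default FALSE).
#' @return the post-processed 8-bit `radiograph`, invisibly, with the
#'   float `feature_map` in attribute `"float_map"`.
#' @export
run_path <- function(image, path, config = pipeline_config(),
                     out_dir = NULL, stem = "image", write_float = FALSE) {
  pre_img <- apply_preprocess(image, path$pre, config)
  maps <- compute_operator_maps(pre_img, path$operator, config)
  if (!path$feature %in% names(maps)) {
    stop("feature ", path$feature, " not produced by operator ", path$operator)
  }
  fmap <- maps[[path$feature]]
  fmap$provenance$preprocess <- path$pre
  fmap$provenance$postprocess <- path$post
  out8 <- apply_postprocess(fmap, path$post)
  if (!is.null(out_dir)) {
    base <- sprintf("%s__%s__%s__%s", stem, path$pre, path$feature, path$post)
    write_raster(out8, file.path(out_dir, paste0(base, ".png")), "8bit")
    if (write_float) {
      write_raster(fmap, file.path(out_dir, paste0(base, ".tiff")), "float")
    }
  }
  structure(out8, float_map = fmap)
}

#' Execute every path of a configuration over a batch of images
#'
#' Computes each operator family once per (image, preprocess) pair and
#' fans the maps out over the post-processing list, writing one 8-bit PNG
#' per path plus a CSV manifest with an MD5 checksum per output. A failing
#' input is recorded in the manifest and does not stop the batch.
#'
#' @param images named list of `radiograph` objects (names become file
#'   stems), or a character vector of DICOM/PNG/TIFF paths.
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return the manifest data.frame (also written to
#'   `out_dir/manifest.csv`): `input`, `pre`, `operator`, `feature`,
#'   `post`, `file`, `md5`, `status`.
#' @export
run_batch <- function(images, config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(images)) {
    paths_in <- images
    images <- lapply(paths_in, function(p) {
      tryCatch({
        if (tolower(tools::file_ext(p)) %in% c("dcm", "dicom")) read_dicom(p)
        else read_raster(p)
      }, error = function(e) e)
    })
    names(images) <- tools::file_path_sans_ext(basename(paths_in))
  }
  if (is.null(names(images))) {
    names(images) <- sprintf("image%03d", seq_along(images))
  }
  paths <- enumerate_paths(config)
  rows <- list()
  for (nm in names(images)) {
    img <- images[[nm]]
    if (inherits(img, "error") || !inherits(img, "radiograph")) {
      msg <- if (inherits(img, "error")) conditionMessage(img) else "unreadable input"
      rows[[length(rows) + 1L]] <-
        data.frame(input = nm, pre = NA, operator = NA, feature = NA,
                   post = NA, file = NA, md5 = NA,
                   status = paste0("failed: ", msg))
      next
    }
    for (pre in unique(paths$pre)) {
      pre_img <- apply_preprocess(img, pre, config)
      ops <- unique(paths$operator[paths$pre == pre])
      for (op in ops) {
        res <- tryCatch(compute_operator_maps(pre_img, op, config),
                        error = function(e) e)
        sel <- which(paths$pre == pre & paths$operator == op)
        for (i in sel) {
          if (inherits(res, "error")) {
            rows[[length(rows) + 1L]] <-
              data.frame(input = nm, pre = pre, operator = op,
                         feature = paths$feature[i], post = paths$post[i],
                         file = NA, md5 = NA,
                         status = paste0("failed: ", conditionMessage(res)))
            next
          }
          fmap <- res[[paths$feature[i]]]
          out8 <- apply_postprocess(fmap, paths$post[i])
          base <- sprintf("%s__%s__%s__%s.png", nm, pre,
                          paths$feature[i], paths$post[i])
          fp <- file.path(out_dir, base)
          write_raster(out8, fp, "8bit")
          rows[[length(rows) + 1L]] <-
            data.frame(input = nm, pre = pre, operator = op,
                       feature = paths$feature[i], post = paths$post[i],
                       file = base, md5 = unname(tools::md5sum(fp)),
                       status = "ok")
        }
      }
    }
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(input = character(), pre = character(), operator = character(),
               feature = character(), post = character(), file = character(),
               md5 = character(), status = character())
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
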