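#' Read a bulk matrix from TSV/CSV or MatrixMarket triplet
#'
#' TSV/CSV files need a header of feature names and a first column of sample
#' IDs. `.mtx` files are read with their sidecar name files
#' `<prefix>.features.txt` and `<prefix>.samples.txt`. Orientation is
#' enforced to samples x features.
#'
#' @param path File path (`.tsv`, `.csv` or `.mtx`).
#' @param orientation Layout of the file on disk.
#' @return Numeric matrix, samples x features, with dimnames.
#' @export
read_bulk_matrix <- function(path,
                             orientation = c("samples_by_features",
                                             "features_by_samples")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (grepl("\\.mtx$", path)) {
    M <- as.matrix(Matrix::readMM(path))
    prefix <- sub("\\.mtx$", "", path)
    ffeat <- paste0(prefix, ".features.txt")
    fsamp <- paste0(prefix, ".samples.txt")
    if (!file.exists(ffeat) || !file.exists(fsamp)) {
      stop("mtx sidecar name files (.features.txt / .samples.txt) are missing",
           call. = FALSE)
    }
    feats <- readLines(ffeat); samps <- readLines(fsamp)
    if (orientation == "features_by_samples") M <- t(M)
    rownames(M) <- samps; colnames(M) <- feats
  } else {
    sep <- if (grepl("\\.csv$", path)) "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                            check.names = FALSE, stringsAsFactors = FALSE)
    if (!all(vapply(df, is.numeric, logical(1)))) {
      bad <- names(df)[!vapply(df, is.numeric, logical(1))][1]
      stop(sprintf("non-numeric column '%s' in %s", bad, path), call. = FALSE)
    }
    M <- as.matrix(df)
    if (orientation == "features_by_samples") M <- t(M)
  }
  dup <- colnames(M)[duplicated(colnames(M))]
  if (length(dup)) {
    stop(sprintf("duplicate feature name(s): %s", paste(unique(dup), collapse = ", ")),
         call. = FALSE)
  }
  M
}

#' Write a bulk matrix as TSV (samples x features)
#' @param mat Numeric matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bulk_matrix <- function(mat, path) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat))) rownames(mat) <- paste0("sample", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- paste0("f", seq_len(ncol(mat)))
  df <- data.frame(sample_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an annotated single-cell reference
#'
#' The count matrix (cells x genes; TSV/CSV/MTX as in [read_bulk_matrix()],
#' cell IDs as row names) is joined to an annotation TSV with columns
#' `cell_id`, `cell_type`, `sample_id`. Cells without annotation are dropped
#' with a message; annotation rows referencing absent cells are ignored with
#' a warning.
#'
#' @param matrix_path Count matrix path.
#' @param annotation_path Annotation TSV path.
#' @return An [single_cell_reference()].
#' @export
read_sc_reference <- function(matrix_path, annotation_path) {
  counts <- read_bulk_matrix(matrix_path)
  ann <- utils::read.table(annotation_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("cell_id", "cell_type", "sample_id")
  if (!all(need %in% names(ann))) {
    stop(sprintf("annotation must have columns %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  missing_cells <- setdiff(ann$cell_id, rownames(counts))
  if (length(missing_cells)) {
    warning(sprintf("%d annotation row(s) reference absent cell IDs; ignored",
                    length(missing_cells)), call. = FALSE)
    ann <- ann[ann$cell_id %in% rownames(counts), , drop = FALSE]
  }
  keep <- rownames(counts) %in% ann$cell_id
  if (!any(keep)) stop("no overlap between matrix cells and annotation", call. = FALSE)
  if (any(!keep)) {
    message(sprintf("dropped %d unannotated cell(s)", sum(!keep)))
  }
  counts <- counts[keep, , drop = FALSE]
  ann <- ann[match(rownames(counts), ann$cell_id), , drop = FALSE]
  single_cell_reference(counts, ann$cell_type, ann$sample_id)
}

#' Select non-RNA bulk features by mean, variation and sparseness
#'
#' Keeps features detected (nonzero) in at least `min_detect_fraction` of
#' samples and with mean at least `min_mean`, then takes the
#' `top_n_variance` most variable among them. Ties in variance break
#' deterministically by feature name.
#'
#' @param Y2 samples x features matrix.
#' @param top_n_variance Number of features to keep (default all surviving).
#' @param min_detect_fraction Minimum fraction of samples with a nonzero
#'   value (default 0).
#' @param min_mean Minimum feature mean (default 0).
#' @return Integer vector of selected column indices (named if `Y2` has
#'   column names), in original column order.
#' @export
select_nonrna_features <- function(Y2, top_n_variance = Inf,
                                   min_detect_fraction = 0, min_mean = 0) {
  Y2 <- as.matrix(Y2)
  nm <- colnames(Y2)
  if (is.null(nm)) nm <- sprintf("f%06d", seq_len(ncol(Y2)))
  detect <- colMeans(Y2 != 0)
  mu <- colMeans(Y2)
  keep <- which(detect >= min_detect_fraction & mu >= min_mean)
  if (!length(keep)) stop("no features survive selection", call. = FALSE)
  if (is.finite(top_n_variance) && length(keep) > top_n_variance) {
    v <- apply(Y2[, keep, drop = FALSE], 2, stats::var)
    ord <- order(-v, nm[keep])
    keep <- keep[ord[seq_len(top_n_variance)]]
    keep <- sort(keep)
  }
  names(keep) <- nm[keep]
  keep
}

#' Map non-RNA features to genes and aggregate
#'
#' With plain (feature_id, gene) rows this is a direct lookup. With
#' coordinate columns (`feature_chrom`, `feature_start`, `gene_chrom`,
#' `gene_start`, `gene_end`, `strand`) a feature is mapped to a gene only if
#' its start lies within the gene body or up to 2 kb upstream of the
#' transcription start site, strand-aware (unstranded rows are treated as
#' `+` with a warning). Coordinates are 1-based inclusive. Features mapping
#' to the same gene are aggregated by sum.
#'
#' @param Y2 samples x features matrix whose columns are feature IDs.
#' @param mapping data.frame with at least `feature_id` and `gene`.
#' @param genes Optional gene subset (e.g. marker genes) to retain.
#' @param upstream Upstream window in bases (default 2000).
#' @return List with `values` (samples x genes aggregated matrix) and
#'   `mapping` (the accepted mapping rows).
#' @export
map_features_to_genes <- function(Y2, mapping, genes = NULL, upstream = 2000L) {
  Y2 <- as.matrix(Y2)
  stopifnot(all(c("feature_id", "gene") %in% names(mapping)))
  coord_cols <- c("feature_chrom", "feature_start", "gene_chrom",
                  "gene_start", "gene_end")
  if (all(coord_cols %in% names(mapping))) {
    strand <- if ("strand" %in% names(mapping)) as.character(mapping$strand)
              else rep(NA_character_, nrow(mapping))
    if (anyNA(strand) || any(!strand %in% c("+", "-"))) {
      bad <- is.na(strand) | !strand %in% c("+", "-")
      warning(sprintf("%d unstranded mapping row(s) treated as '+'", sum(bad)),
              call. = FALSE)
      strand[bad] <- "+"
    }
    same_chrom <- mapping$feature_chrom == mapping$gene_chrom
    plus_ok <- strand == "+" &
      mapping$feature_start >= mapping$gene_start - upstream &
      mapping$feature_start <= mapping$gene_end
    minus_ok <- strand == "-" &
      mapping$feature_start >= mapping$gene_start &
      mapping$feature_start <= mapping$gene_end + upstream
    mapping <- mapping[same_chrom & (plus_ok | minus_ok), , drop = FALSE]
  }
  mapping <- mapping[mapping$feature_id %in% colnames(Y2), , drop = FALSE]
  if (!is.null(genes)) mapping <- mapping[mapping$gene %in% genes, , drop = FALSE]
  if (!nrow(mapping)) stop("no mappable features", call. = FALSE)
  gene_levels <- unique(mapping$gene)
  out <- matrix(0, nrow(Y2), length(gene_levels),
                dimnames = list(rownames(Y2), gene_levels))
  for (i in seq_len(nrow(mapping))) {
    g <- mapping$gene[i]
    out[, g] <- out[, g] + Y2[, mapping$feature_id[i]]
  }
  list(values = out, mapping = mapping)
}

# ---- model / state serialization (plain-text directory layout) --------------

write_matrix_list <- function(lst, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(lst)) {
    x <- lst[[nm]]
    if (is.list(x)) {
      for (i in seq_along(x)) {
        utils::write.table(x[[i]], file.path(dir, sprintf("%s_%d.tsv", nm, i)),
                           sep = "\t", quote = FALSE, row.names = FALSE,
                           col.names = FALSE)
      }
    } else {
      utils::write.table(as.matrix(x), file.path(dir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
    }
  }
  invisible(dir)
}

read_plain_matrix <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
}

#' Save / load a trained deconvolution model as a plain-text checkpoint
#'
#' Weight matrices are written as headerless TSVs inside `dir` with a JSON
#' attribute block for dimensions, configuration and feature names.
#'
#' @param model A `deconv_model`.
#' @param dir Checkpoint directory.
#' @return `read_deconv_model` returns the model; `write_deconv_model`
#'   returns `dir` invisibly.
#' @export
write_deconv_model <- function(model, dir) {
  stopifnot(inherits(model, "deconv_model"))
  p <- model$params
  write_matrix_list(list(enc_W = p$enc_W,
                         enc_b = lapply(p$enc_b, function(b) matrix(b, nrow = 1)),
                         S1 = p$S1, S2 = p$S2, dec1 = p$dec1, dec2 = p$dec2),
                    dir)
  meta <- list(m1 = p$m1, m2 = p$m2, k = p$k, alpha = p$alpha,
               config = unclass(model$config),
               stats1 = model$stats1, stats2 = model$stats2,
               cell_types = model$cell_types,
               feature_names1 = model$feature_names1,
               feature_names2 = model$feature_names2,
               spec1 = model$spec1$name, spec2 = model$spec2$name,
               history = model$history)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_deconv_model
#' @export
read_deconv_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  rd <- function(nm) read_plain_matrix(file.path(dir, paste0(nm, ".tsv")))
  rd_list <- function(nm) lapply(1:5, function(i) rd(sprintf("%s_%d", nm, i)))
  params <- list(enc_W = rd_list("enc_W"),
                 enc_b = lapply(rd_list("enc_b"), function(m) as.numeric(m)),
                 S1 = rd("S1"), S2 = rd("S2"),
                 dec1 = rd_list("dec1"), dec2 = rd_list("dec2"),
                 m1 = meta$m1, m2 = meta$m2, k = meta$k, alpha = meta$alpha)
  cfg <- meta$config
  cfg <- train_config(epochs = cfg$epochs, batch_size = cfg$batch_size,
                      learning_rate = cfg$learning_rate,
                      recon_weight = cfg$recon_weight,
                      adapt_steps = cfg$adapt_steps, adapt_lr = cfg$adapt_lr,
                      anchor_weight = cfg$anchor_weight,
                      celu_alpha = cfg$celu_alpha, hidden = cfg$hidden,
                      dec_hidden = cfg$dec_hidden, seed = cfg$seed)
  structure(list(params = params, history = as.data.frame(meta$history),
                 config = cfg,
                 stats1 = lapply(meta$stats1, as.numeric),
                 stats2 = lapply(meta$stats2, as.numeric),
                 cell_types = meta$cell_types,
                 feature_names1 = meta$feature_names1,
                 feature_names2 = meta$feature_names2,
                 spec1 = modality_spec(meta$spec1),
                 spec2 = modality_spec(meta$spec2)),
            class = "deconv_model")
}
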