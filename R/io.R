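#' Read and write NIfTI-1 volumes
#'
#' Thin wrappers over RNifti that populate the package's spatial containers.
#' `read_volume4d()` requires a 4-dimensional image and a positive temporal
#' spacing (`pixdim[4]`, seconds). Writers store the affine in both the sform
#' and qform; `write_volume4d()` stores data as float64 so a write/read
#' round-trip is bitwise lossless, while `write_stat_map()` uses float32
#' (round-trips within float32 rounding).
#'
#' @param path File path to a `.nii` or `.nii.gz` file.
#' @param vol A `volume4d`.
#' @param map A `stat_map`.
#' @param mask A `brain_mask`.
#' @param parc A `parcellation`.
#' @param kind `kind` to tag the map read by `read_stat_map()` with.
#' @param region_ids,names Optional atlas metadata for `read_parcellation()`.
#' @return Readers return the corresponding container; writers return the
#'   path, invisibly.
#' @name nifti-io
NULL

read_nifti_checked <- function(path, ndim) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != ndim)
    stop("expected ", ndim, "D image, got ", length(d), "D: ", path,
         call. = FALSE)
  img
}

nifti_affine <- function(img) {
  aff <- unname(structure(RNifti::xform(img), imagedim = NULL, code = NULL))
  attributes(aff) <- list(dim = dim(aff))
  aff
}

#' @rdname nifti-io
#' @export
read_volume4d <- function(path) {
  img <- read_nifti_checked(path, 4L)
  tr <- RNifti::pixdim(img)[4]
  if (!is.finite(tr) || tr <= 0)
    stop("header pixdim[4] (repetition time) must be > 0, got ", tr,
         call. = FALSE)
  volume4d(array(as.vector(img), dim(img)), nifti_affine(img), tr)
}

#' @rdname nifti-io
#' @export
write_volume4d <- function(vol, path) {
  stopifnot(inherits(vol, "volume4d"))
  vx <- sqrt(colSums(vol$affine[1:3, 1:3]^2))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- c(vx, vol$tr)
  RNifti::`sform<-`(img, structure(vol$affine, code = 2L)) -> img
  RNifti::`qform<-`(img, structure(vol$affine, code = 2L)) -> img
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

write_nifti_3d <- function(data, affine, path, datatype) {
  vx <- sqrt(colSums(affine[1:3, 1:3]^2))
  img <- RNifti::asNifti(data * 1)
  RNifti::pixdim(img) <- vx
  RNifti::`sform<-`(img, structure(affine, code = 2L)) -> img
  RNifti::`qform<-`(img, structure(affine, code = 2L)) -> img
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' @rdname nifti-io
#' @export
read_stat_map <- function(path, kind = "tmap") {
  img <- read_nifti_checked(path, 3L)
  stat_map(array(as.vector(img), dim(img)), nifti_affine(img), kind)
}

#' @rdname nifti-io
#' @export
write_stat_map <- function(map, path) {
  stopifnot(inherits(map, "stat_map"))
  write_nifti_3d(map$data, map$affine, path, "float")
}

#' @rdname nifti-io
#' @export
read_brain_mask <- function(path) {
  img <- read_nifti_checked(path, 3L)
  brain_mask(array(as.vector(img) != 0, dim(img)), nifti_affine(img))
}

#' @rdname nifti-io
#' @export
write_brain_mask <- function(mask, path) {
  stopifnot(inherits(mask, "brain_mask"))
  write_nifti_3d(array(as.integer(mask$data), dim(mask$data)), mask$affine,
                 path, "uint8")
}

#' @rdname nifti-io
#' @export
read_parcellation <- function(path, region_ids = NULL, names = NULL) {
  img <- read_nifti_checked(path, 3L)
  parcellation(array(as.integer(round(as.vector(img))), dim(img)),
               nifti_affine(img), region_ids = region_ids, names = names)
}

#' @rdname nifti-io
#' @export
write_parcellation <- function(parc, path) {
  stopifnot(inherits(parc, "parcellation"))
  write_nifti_3d(parc$labels, parc$affine, path, "int16")
}

subject_required_cols <- c("subject_id", "group", "age", "education", "tiv",
                           "bai", "bdi", "ee", "dp", "pa")

#' Load a subject covariate and score table
#'
#' Reads a delimited text table with one row per subject: `subject_id`,
#' `group` (`burnout` or `control`), the nuisance covariates `age`,
#' `education`, `tiv`, `bai`, `bdi`, and the Maslach Burnout Inventory
#' subscales `ee`, `dp`, `pa` (emotional exhaustion, depersonalization,
#' personal accomplishment).
#'
#' @param path Path to a comma- or tab-delimited file with a header.
#' @return A tibble with the ten validated columns, `group` as a factor with
#'   levels `burnout`, `control`.
#' @export
load_subject_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(subject_required_cols, tolower(names(tab)))
  if (length(missing))
    stop("subject table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  names(tab) <- tolower(names(tab))
  tab <- tab[subject_required_cols]
  validate_subject_table(tab)
}

validate_subject_table <- function(tab) {
  tab$subject_id <- as.character(tab$subject_id)
  if (anyDuplicated(tab$subject_id))
    stop("duplicate subject_id: ",
         paste(unique(tab$subject_id[duplicated(tab$subject_id)]),
               collapse = ", "), call. = FALSE)
  bad_group <- setdiff(unique(as.character(tab$group)), c("burnout", "control"))
  if (length(bad_group))
    stop("`group` must be 'burnout' or 'control'; found: ",
         paste(bad_group, collapse = ", "), call. = FALSE)
  tab$group <- factor(as.character(tab$group), levels = c("burnout", "control"))
  num_cols <- setdiff(subject_required_cols, c("subject_id", "group"))
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(tab[[cl]]))
    if (anyNA(v))
      stop("column `", cl, "` contains unparseable numeric values",
           call. = FALSE)
    tab[[cl]] <- v
  }
  if (any(tab$ee < 0 | tab$dp < 0 | tab$pa < 0 | tab$bai < 0 | tab$bdi < 0))
    stop("scores must be non-negative", call. = FALSE)
  tibble::as_tibble(tab)
}

#' Read a GMT-like gene category annotation file
#'
#' One category per line: category id, description/aspect, then the annotated
#' gene symbols, all tab-separated. The second field is parsed as the GO
#' aspect when it is one of `BP`, `CC`, `MF` (a leading description is kept
#' verbatim otherwise).
#'
#' @param path Path to the annotation file.
#' @return A long tibble with columns `category_id`, `aspect`, `gene` (one
#'   row per direct gene-to-category annotation).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("malformed annotation line (need id, aspect, >=1 gene): ",
           substr(ln, 1, 40), call. = FALSE)
    tibble::tibble(category_id = f[1], aspect = f[2],
                   gene = unique(f[-(1:2)]))
  })
  dplyr::bind_rows(rows)
}

#' @rdname read_annotations
#' @param annotations Long tibble as returned by `read_annotations()`.
#' @export
write_annotations <- function(annotations, path) {
  sp <- split(annotations$gene, annotations$category_id)
  asp <- vapply(split(annotations$aspect, annotations$category_id),
                function(a) a[[1]], character(1))
  lines <- vapply(names(sp), function(id) {
    paste(c(id, asp[[id]], sp[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
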