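# Dataset I/O (extended XYZ and an RDS container), unit conversion and
# reproducible splits.

#' Read a labelled dataset from an extended-XYZ file
#'
#' Parses the de-facto extended-XYZ dialect: per frame, an atom count line,
#' a comment line carrying `key=value` entries (the total energy under the
#' key `energy`, in kcal/mol by convention), and per-atom rows
#' `species x y z fx fy fz` with the forces in the last three columns
#' (kcal mol^-1 A^-1).  Atom order is preserved; all frames must share the
#' same atom count and species sequence.
#'
#' @param path file to read.
#' @param convertFromEV if TRUE, energies/forces are converted from
#'   eV / eV A^-1 to the package's kcal-based units.
#' @return A [MolecularDataset-class].
#' @seealso [writeExtXYZ()] for the inverse, lossless to double precision.
#' @export
readExtXYZ <- function(path, convertFromEV = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  pos <- 1L; frame <- 0L
  Zref <- NULL
  coordsL <- list(); forcesL <- list(); energiesL <- numeric(0)
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    frame <- frame + 1L
    nat <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(nat) || nat < 1L)
      stop("frame ", frame, ": malformed atom-count line")
    if (pos + 1L + nat > length(lines))
      stop("frame ", frame, ": truncated frame (", nat, " atom rows expected)")
    comment <- lines[pos + 1L]
    kv <- .parseKeyValues(comment)
    if (is.null(kv[["energy"]]))
      stop("frame ", frame, ": comment line carries no energy=... entry")
    en <- as.numeric(kv[["energy"]])
    rows <- lines[pos + 1L + seq_len(nat)]
    tok <- strsplit(trimws(rows), "[[:space:]]+")
    ncols <- lengths(tok)
    if (any(ncols < 7L))
      stop("frame ", frame, ": atom row(s) with fewer than 7 columns ",
           "(species x y z fx fy fz expected)")
    sp <- vapply(tok, `[[`, "", 1L)
    num <- matrix(as.numeric(unlist(lapply(tok, function(t) t[2:7]))),
                  ncol = 6L, byrow = TRUE)
    if (any(!is.finite(num)))
      stop("frame ", frame, ": non-numeric coordinate/force fields")
    Z <- .symbolToZ(sp)
    if (is.null(Zref)) Zref <- Z
    else if (length(Z) != length(Zref) || any(Z != Zref))
      stop("frame ", frame, ": atom count or species sequence differs ",
           "from frame 1")
    coordsL[[frame]] <- num[, 1:3, drop = FALSE]
    forcesL[[frame]] <- num[, 4:6, drop = FALSE]
    energiesL[frame] <- en
    pos <- pos + 2L + nat
  }
  if (frame == 0L) stop("no frames found in ", path)
  n <- length(Zref)
  coords <- array(unlist(coordsL), dim = c(n, 3L, frame))
  forcesA <- array(unlist(forcesL), dim = c(n, 3L, frame))
  if (convertFromEV) {
    fac <- 1 / gdmlrConstants$eV_per_kcalmol
    energiesL <- energiesL * fac
    forcesA <- forcesA * fac
  }
  molecularDataset(Zref, coords, energiesL, forcesA,
                   name = basename(path),
                   provenance = paste0("read from ", path,
                                       if (convertFromEV) " (eV converted)" else ""))
}

.parseKeyValues <- function(line) {
  # key=value tokens; values may be double-quoted (e.g. Properties strings)
  out <- list()
  pat <- '([A-Za-z_][A-Za-z0-9_]*)=("([^"]*)"|[^[:space:]]+)'
  m <- gregexpr(pat, line, perl = TRUE)[[1]]
  if (m[1] == -1) return(out)
  starts <- as.integer(m); lens <- attr(m, "match.length")
  for (t in seq_along(starts)) {
    tokstr <- substr(line, starts[t], starts[t] + lens[t] - 1L)
    eq <- regexpr("=", tokstr, fixed = TRUE)
    key <- substr(tokstr, 1L, eq - 1L)
    val <- substr(tokstr, eq + 1L, nchar(tokstr))
    val <- gsub('^"|"$', "", val)
    out[[key]] <- val
  }
  out
}

#' Write a labelled dataset as extended XYZ
#'
#' Inverse of [readExtXYZ()]: energies go on the comment line
#' (`energy=...`), forces in the last three per-atom columns.  Numeric
#' fields are printed with 17 significant digits so a read/write round trip
#' is lossless to double precision.
#'
#' @param dataset a [MolecularDataset-class] with at least one frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeExtXYZ <- function(dataset, path) {
  stopifnot(is(dataset, "MolecularDataset"))
  if (nFrames(dataset) < 1L) stop("dataset has no configurations to write")
  n <- nAtoms(dataset)
  sym <- .elementSymbols[dataset@Z]
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nFrames(dataset))) {
    xyz <- dataset@coords[, , f]; fr <- dataset@forces[, , f]
    writeLines(as.character(n), con)
    writeLines(sprintf(
      'Properties=species:S:1:pos:R:3:forces:R:3 energy=%.17g',
      dataset@energies[f]), con)
    writeLines(sprintf("%-3s %.17g %.17g %.17g %.17g %.17g %.17g",
                       sym, xyz[, 1], xyz[, 2], xyz[, 3],
                       fr[, 1], fr[, 2], fr[, 3]), con)
  }
  invisible(path)
}

#' Read / write datasets with format chosen by file extension
#'
#' `.xyz` / `.extxyz` files go through the extended-XYZ reader/writer;
#' `.rds` files use the package's binary container, a serialized list with
#' named fields `Z`, `R`, `E`, `F`, `meta` and a schema tag (convenient for
#' large datasets where text parsing would dominate).
#'
#' @param path file path; the extension selects the format.
#' @param dataset a [MolecularDataset-class] (for `writeDataset`).
#' @param ... passed to [readExtXYZ()].
#' @return `readDataset` returns a [MolecularDataset-class].
#' @export
readDataset <- function(path, ...) {
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    obj <- readRDS(path)
    if (!identical(obj$schema, "gdmlr-dataset-1"))
      stop("not a gdmlr dataset container: ", path)
    molecularDataset(obj$Z, obj$R, obj$E, obj$F,
                     name = obj$meta$name %||% basename(path),
                     provenance = obj$meta$provenance %||% "")
  } else readExtXYZ(path, ...)
}

#' @rdname readDataset
#' @export
writeDataset <- function(dataset, path) {
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    saveRDS(list(schema = "gdmlr-dataset-1", Z = dataset@Z,
                 R = dataset@coords, E = dataset@energies,
                 F = dataset@forces,
                 meta = list(name = dataset@name,
                             provenance = dataset@provenance)),
            path)
    invisible(path)
  } else writeExtXYZ(dataset, path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reproducible train/validation/test split
#'
#' Samples three disjoint index sets uniformly without replacement using
#' R's Mersenne-Twister stream seeded with `seed` (recorded in the result);
#' the same seed always yields the same split.
#'
#' @param dataset a [MolecularDataset-class].
#' @param nTrain,nValid,nTest requested sizes.  `nTest = NA` assigns all
#'   remaining frames to the test set.
#' @param seed integer PRNG seed.
#' @return List with integer vectors `train`, `validation`, `test` (1-based
#'   frame indices) and the `seed`.
#' @export
splitDataset <- function(dataset, nTrain, nValid, nTest = NA, seed = 1L) {
  nf <- nFrames(dataset)
  nTrain <- as.integer(nTrain); nValid <- as.integer(nValid)
  rest <- is.na(nTest)
  if (rest) nTest <- nf - nTrain - nValid else nTest <- as.integer(nTest)
  if (nTrain < 0L || nValid < 0L || nTest < 0L)
    stop("split sizes must be nonnegative")
  if (nTrain + nValid + nTest > nf)
    stop("oversubscribed split: ", nTrain + nValid + nTest,
         " indices requested from ", nf, " frames")
  .withSeed(seed, {
    perm <- sample.int(nf, nTrain + nValid + nTest)
    list(train = sort(perm[seq_len(nTrain)]),
         validation = sort(perm[nTrain + seq_len(nValid)]),
         test = sort(perm[nTrain + nValid + seq_len(nTest)]),
         seed = as.integer(seed))
  })
}

#' Split a dataset by molecular extent
#'
#' Partitions frames into compact and extended subsets by the distance
#' between the two furthest atoms: a frame is "extended" iff its maximum
#' interatomic distance exceeds `threshold` (computed exactly over all atom
#' pairs).  Used to probe transferability between conformational regimes.
#'
#' @param dataset a [MolecularDataset-class].
#' @param threshold extent threshold in Angstrom (> 0).
#' @return List with integer index vectors `compact` and `extended`
#'   (1-based) and the per-frame `extent` in Angstrom.
#' @export
splitByExtent <- function(dataset, threshold) {
  stopifnot(threshold > 0)
  nf <- nFrames(dataset)
  ext <- vapply(seq_len(nf),
                function(f) max(stats::dist(dataset@coords[, , f])),
                numeric(1))
  list(compact = which(ext <= threshold), extended = which(ext > threshold),
       extent = ext)
}
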