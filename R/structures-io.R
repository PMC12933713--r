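#' Read a protein structure from a PDB file
#'
#' Parses ATOM records of a single chain into an atomic data model. HETATM
#' records, waters and alternate locations other than blank/'A' are dropped;
#' hydrogens are retained (flagged `is_heavy = FALSE`). Insertion codes are
#' appended to the residue index representation (e.g. `"52A"`). Only the
#' first MODEL of a multi-model file is read; use [read_trajectory()] for
#' all frames.
#'
#' @param path path to a PDB file.
#' @param chain optional single chain identifier; default keeps all chains.
#' @param het keep HETATM records as well (default `FALSE`).
#' @return A `surfibs_structure`: list with tibbles `atoms` (serial, name,
#'   element, residue_name, residue_index, chain_id, x, y, z, is_heavy) and
#'   `residues` (chain_id, residue_index, residue_name), residues ordered by
#'   chain then author numbering.
#' @export
read_pdb <- function(path, chain = NULL, het = FALSE) {
  if (!file.exists(path)) stop_surfibs(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1] - 1)]
  rec <- substr(lines, 1, 6)
  keep <- rec == "ATOM  " | (het & rec == "HETATM")
  lines <- lines[keep]
  atoms <- parse_atom_lines(lines, chain)
  if (nrow(atoms) == 0)
    stop_surfibs(sprintf("no ATOM records%s in %s",
                         if (is.null(chain)) "" else paste0(" for chain ", chain), path))
  as_structure(atoms)
}

parse_atom_lines <- function(lines, chain = NULL) {
  if (length(lines) == 0) {
    return(tibble(serial = integer(), name = character(), element = character(),
                  residue_name = character(), residue_index = character(),
                  chain_id = character(), x = double(), y = double(), z = double(),
                  is_heavy = logical()))
  }
  altloc <- substr(lines, 17, 17)
  lines <- lines[altloc %in% c(" ", "A")]
  name <- trimws(substr(lines, 13, 16))
  resn <- trimws(substr(lines, 18, 20))
  ch <- substr(lines, 22, 22)
  if (!is.null(chain)) {
    sel <- ch == chain
    lines <- lines[sel]; name <- name[sel]; resn <- resn[sel]; ch <- ch[sel]
  }
  drop <- resn %in% c("HOH", "WAT")
  lines <- lines[!drop]; name <- name[!drop]; resn <- resn[!drop]; ch <- ch[!drop]
  if (length(lines) == 0) return(parse_atom_lines(character(0)))
  num <- function(a, b, what) {
    v <- suppressWarnings(as.numeric(substr(lines, a, b)))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop_surfibs(sprintf("unparseable %s field in PDB line: %s", what, lines[bad[1]]))
    v
  }
  x <- num(31, 38, "x"); y <- num(39, 46, "y"); z <- num(47, 54, "z")
  serial <- suppressWarnings(as.integer(substr(lines, 7, 11)))
  serial[is.na(serial)] <- seq_along(lines)[is.na(serial)]
  resi <- trimws(paste0(trimws(substr(lines, 23, 26)), trimws(substr(lines, 27, 27))))
  elem <- trimws(substr(lines, 77, 78))
  guess <- sub("^[0-9]*", "", name)
  guess <- toupper(substr(guess, 1, 1))
  elem <- ifelse(elem == "", guess, toupper(elem))
  tibble(serial = serial, name = name, element = elem, residue_name = resn,
         residue_index = resi, chain_id = ch, x = x, y = y, z = z,
         is_heavy = !(elem %in% c("H", "D")))
}

as_structure <- function(atoms) {
  key <- paste(atoms$chain_id, atoms$residue_index, atoms$residue_name)
  res <- atoms[!duplicated(key), c("chain_id", "residue_index", "residue_name")]
  ord <- order(res$chain_id,
               suppressWarnings(as.integer(sub("[A-Za-z]*$", "", res$residue_index))),
               res$residue_index)
  res <- res[ord, ]
  res$residue <- seq_len(nrow(res))
  atoms$residue <- res$residue[match(key, paste(res$chain_id, res$residue_index,
                                                res$residue_name))]
  structure(list(atoms = atoms, residues = tibble::as_tibble(res)),
            class = "surfibs_structure")
}

#' @export
print.surfibs_structure <- function(x, ...) {
  cat(sprintf("<surfibs_structure> %d atoms (%d heavy), %d residues, chains: %s\n",
              nrow(x$atoms), sum(x$atoms$is_heavy), nrow(x$residues),
              paste(unique(x$residues$chain_id), collapse = ",")))
  invisible(x)
}

#' Write a structure (or one frame) as PDB text
#'
#' @param structure a `surfibs_structure`.
#' @param path output path; when `NULL` the lines are returned invisibly.
#' @param model optional MODEL number to wrap the records in.
#' @return the character vector of PDB lines, invisibly.
#' @export
write_pdb <- function(structure, path = NULL, model = NULL) {
  a <- structure$atoms
  icode <- sub("^-?[0-9]*", "", a$residue_index)
  resnum <- as.integer(sub("[A-Za-z]*$", "", a$residue_index))
  name4 <- ifelse(nchar(a$name) >= 4, substr(a$name, 1, 4),
                  sprintf(" %-3s", a$name))
  lines <- sprintf("ATOM  %5d %4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   a$serial %% 100000, name4, a$residue_name, a$chain_id,
                   resnum, ifelse(icode == "", " ", icode),
                   a$x, a$y, a$z, 1, 0, a$element)
  if (!is.null(model)) lines <- c(sprintf("MODEL %8d", model), lines, "ENDMDL")
  if (!is.null(path)) writeLines(c(lines, if (is.null(model)) "END"), path)
  invisible(lines)
}

#' Read a multi-MODEL PDB trajectory
#'
#' @param path path to a PDB file with MODEL/ENDMDL blocks.
#' @param het keep HETATM records (default `TRUE`: membrane mimetics are
#'   often written as heteroatoms).
#' @return list with `structure` (first frame, all residues) and `frames`,
#'   a list of n_atoms x 3 coordinate matrices, one per MODEL.
#' @export
read_trajectory <- function(path, het = TRUE) {
  if (!file.exists(path)) stop_surfibs(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  if (length(starts) == 0) { starts <- 1; ends <- length(lines) }
  if (length(starts) != length(ends))
    stop_surfibs("unbalanced MODEL/ENDMDL records")
  rec_ok <- function(l) grepl(if (het) "^(ATOM  |HETATM)" else "^ATOM  ", l)
  frames <- vector("list", length(starts))
  struct <- NULL
  for (f in seq_along(starts)) {
    blk <- lines[starts[f]:ends[f]]
    blk <- blk[rec_ok(blk)]
    atoms <- parse_atom_lines(blk)
    if (is.null(struct)) struct <- as_structure(atoms)
    if (nrow(atoms) != nrow(struct$atoms))
      stop_surfibs(sprintf("frame %d has %d atoms, expected %d",
                           f, nrow(atoms), nrow(struct$atoms)))
    frames[[f]] <- as.matrix(atoms[, c("x", "y", "z")])
  }
  list(structure = struct, frames = frames)
}

#' Read an MSMS surface from paired .vert/.face files
#'
#' MSMS writes vertex lines `x y z nx ny nz ...` and 1-based triangle lines
#' `i j k ...` after three header lines. Indices are converted to this
#' package's convention; all-zero normals are recomputed from the face
#' geometry.
#'
#' @param vert_path,face_path paths to the `.vert` and `.face` files.
#' @return a [surface_mesh()].
#' @export
read_msms_surface <- function(vert_path, face_path) {
  vl <- read_msms_body(vert_path)
  fl <- read_msms_body(face_path)
  nv <- vl$count
  if (length(vl$rows) != nv)
    stop_surfibs(sprintf("%s: header declares %d vertices, body has %d",
                         vert_path, nv, length(vl$rows)))
  if (length(fl$rows) != fl$count)
    stop_surfibs(sprintf("%s: header declares %d faces, body has %d",
                         face_path, fl$count, length(fl$rows)))
  vm <- do.call(rbind, lapply(vl$rows, function(r) r[1:6]))
  fm <- do.call(rbind, lapply(fl$rows, function(r) as.integer(r[1:3])))
  bad <- which(fm < 1 | fm > nv, arr.ind = TRUE)
  if (nrow(bad))
    stop_surfibs(sprintf("face %d references vertex %d of a %d-vertex file",
                         bad[1, 1], fm[bad[1, 1], bad[1, 2]], nv))
  normals <- vm[, 4:6, drop = FALSE]
  if (all(abs(normals) < 1e-12)) normals <- NULL
  mesh <- surface_mesh(vm[, 1:3, drop = FALSE], fm, normals = normals)
  normalize_winding(mesh)
}

read_msms_body <- function(path) {
  if (!file.exists(path)) stop_surfibs(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- as.numeric(strsplit(trimws(lines[1]), "\\s+")[[1]])
  rows <- lapply(lines[-1], function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  list(count = header[1], rows = rows)
}

#' Read or write a mesh as ascii PLY or OFF
#'
#' The format is inferred from the file extension. Coordinates are written
#' with 9 significant digits so that a write-then-read round trip
#' reproduces the mesh; winding is normalized to consistent
#' counter-clockwise (outward for closed meshes) on read.
#'
#' @param path file path ending in `.ply` or `.off`.
#' @param mesh a [surface_mesh()] (for writing).
#' @return the mesh read back / invisibly the path written.
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!file.exists(path)) stop_surfibs(sprintf("file not found: %s", path))
  mesh <- switch(ext,
    ply = read_ply(path),
    off = read_off(path),
    stop_surfibs(sprintf("unsupported mesh extension: .%s", ext)))
  normalize_winding(mesh)
}

#' @rdname read_mesh
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    ply = write_ply(mesh, path),
    off = write_off(mesh, path),
    stop_surfibs(sprintf("unsupported mesh extension: .%s", ext)))
  invisible(path)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3 || trimws(lines[1]) != "ply")
    stop_surfibs(sprintf("malformed PLY file: %s", path))
  hend <- match("end_header", trimws(lines))
  if (is.na(hend)) stop_surfibs(sprintf("malformed PLY file (no end_header): %s", path))
  header <- trimws(lines[1:hend])
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex ", header, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face ", header, value = TRUE)))
  if (length(nv) != 1 || length(nf) != 1)
    stop_surfibs(sprintf("malformed PLY header: %s", path))
  body <- lines[-(1:hend)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < nv + nf) stop_surfibs(sprintf("truncated PLY file: %s", path))
  vp <- grep("^property ", header, value = TRUE)
  vrows <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  vm <- do.call(rbind, lapply(vrows, function(r) as.numeric(r)))
  frows <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  fm <- do.call(rbind, lapply(frows, function(r) as.integer(r)))
  if (any(fm[, 1] != 3)) stop_surfibs("only triangular PLY faces are supported")
  normals <- NULL
  has_n <- all(c("property float nx", "property float ny", "property float nz") %in% header) ||
    all(c("property double nx", "property double ny", "property double nz") %in% header)
  if (has_n && ncol(vm) >= 6) normals <- vm[, 4:6, drop = FALSE]
  surface_mesh(vm[, 1:3, drop = FALSE], fm[, 2:4, drop = FALSE] + 1L, normals = normals)
}

write_ply <- function(mesh, path, scalar = NULL, scalar_name = "quality") {
  V <- mesh$vertices
  F <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(V)),
               "property double x", "property double y", "property double z",
               "property double nx", "property double ny", "property double nz",
               if (!is.null(scalar)) sprintf("property double %s", scalar_name),
               sprintf("element face %d", nrow(F)),
               "property list uchar int vertex_indices", "end_header"), con)
  vm <- cbind(V, mesh$normals, scalar)
  writeLines(apply(vm, 1, function(r) paste(sprintf("%.9g", r), collapse = " ")), con)
  writeLines(sprintf("3 %d %d %d", F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L), con)
}

read_off <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  if (length(lines) < 2 || trimws(lines[1]) != "OFF")
    stop_surfibs(sprintf("malformed OFF file: %s", path))
  counts <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  body <- lines[-(1:2)]
  if (length(body) < nv + nf) stop_surfibs(sprintf("truncated OFF file: %s", path))
  vm <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"), as.numeric))
  fm <- do.call(rbind, lapply(strsplit(trimws(body[nv + seq_len(nf)]), "\\s+"),
                              function(r) as.integer(r)))
  if (any(fm[, 1] != 3)) stop_surfibs("only triangular OFF faces are supported")
  surface_mesh(vm[, 1:3, drop = FALSE], fm[, 2:4, drop = FALSE] + 1L)
}

write_off <- function(mesh, path) {
  V <- mesh$vertices
  F <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("OFF", sprintf("%d %d 0", nrow(V), nrow(F))), con)
  writeLines(apply(V, 1, function(r) paste(sprintf("%.9g", r), collapse = " ")), con)
  writeLines(sprintf("3 %d %d %d", F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L), con)
}

#' Read / write residue-level label tables
#'
#' Plain TSV with columns chain, residue_index, residue_name, label (0/1).
#'
#' @param path TSV path.
#' @param labels a residue-level label tibble (see [residue_to_surface()]).
#' @return a tibble with the four columns.
#' @export
read_label_table <- function(path) {
  tb <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character", "character", "integer"))
  tibble::as_tibble(setNames(tb, c("chain_id", "residue_index", "residue_name", "label")))
}

#' @rdname read_label_table
#' @export
write_label_table <- function(labels, path) {
  utils::write.table(labels[, c("chain_id", "residue_index", "residue_name", "label")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
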