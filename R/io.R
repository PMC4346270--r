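#' Read a bead annotation table
#'
#' CSV with columns \code{residue_name}, \code{bead_name}, \code{species},
#' \code{roles} (semicolon-joined, may be empty) and \code{vdw_radius_A}.
#' A row with \code{bead_name == "*"} is a fallback for any bead of that
#' residue without an exact row.
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("residue_name", "bead_name", "species", "roles", "vdw_radius_A")
  missing_cols <- setdiff(required, names(ann))
  if (length(missing_cols))
    stop("annotation table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  ann$roles[is.na(ann$roles)] <- ""
  ann
}

#' Load and annotate a membrane system
#'
#' Reads a structure in GRO or PDB dialect (chosen by file extension) and
#' annotates every bead with species, roles and van der Waals radius from the
#' annotation table, keyed on (residue_name, bead_name) with a \code{"*"}
#' bead-name fallback per residue. Residue numbering is taken verbatim from
#' the structure, so crystal-structure residue labels map directly. Molecule
#' identity is derived from the annotation: all PROTEIN beads form one
#' molecule; every other species starts a new molecule at each change of
#' residue.
#'
#' @param structure_path path to a .gro or .pdb file.
#' @param annotation_path path to the annotation CSV
#'   (see \code{\link{read_annotation}}).
#' @return a \code{membrane_system}. Beads of a known residue with no exact
#'   or fallback bead row are annotated from the residue's first row with no
#'   roles and reported with a warning.
#' @export
load_system <- function(structure_path, annotation_path) {
  ann <- read_annotation(annotation_path)
  ext <- tolower(tools::file_ext(structure_path))
  raw <- switch(ext,
    gro = read_gro(structure_path),
    pdb = read_pdb_nm(structure_path),
    stop("unsupported structure format '.", ext, "' (expected .gro or .pdb)"))
  beads <- raw$beads

  unknown <- setdiff(unique(beads$residue_name), unique(ann$residue_name))
  if (length(unknown))
    stop("no annotation for residue name(s): ",
         paste(unknown, collapse = ", "))

  key <- paste(beads$residue_name, beads$name, sep = "\r")
  akey <- paste(ann$residue_name, ann$bead_name, sep = "\r")
  hit <- match(key, akey)
  fb <- match(paste(beads$residue_name, "*", sep = "\r"), akey)
  use_fb <- is.na(hit) & !is.na(fb)
  hit[use_fb] <- fb[use_fb]
  unmatched <- is.na(hit)
  if (any(unmatched)) {
    first_row <- match(beads$residue_name, ann$residue_name)
    hit[unmatched] <- first_row[unmatched]
    warning(sum(unmatched), " bead(s) had no (residue, bead) annotation row; ",
            "annotated by residue with no roles: ",
            paste(utils::head(unique(paste0(beads$residue_name[unmatched], "/",
                                            beads$name[unmatched])), 8),
                  collapse = ", "))
  }
  beads$species <- ann$species[hit]
  beads$roles <- ann$roles[hit]
  beads$roles[unmatched] <- ""
  beads$vdw_radius_A <- ann$vdw_radius_A[hit]

  # Molecule identity: protein is one molecule; lipids/solvent one per residue.
  is_prot <- beads$species == "PROTEIN"
  res_change <- c(TRUE, beads$residue_id[-1] != beads$residue_id[-nrow(beads)] |
                    beads$residue_name[-1] != beads$residue_name[-nrow(beads)])
  mol <- cumsum(res_change | is_prot != c(is_prot[1], is_prot[-length(is_prot)]))
  mol[is_prot] <- 0L
  mol <- match(mol, unique(mol))
  beads$molecule_id <- mol

  system <- membrane_system(beads, raw$box)
  system$positions <- raw$positions
  system
}

# --- GRO dialect (fixed columns, nm) ---------------------------------------

read_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("malformed GRO file (too short): ", path)
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) stop("malformed GRO file at line 2: atom count expected")
  if (length(lines) < 2L + n + 1L)
    stop("malformed GRO file: ", n, " atoms declared, file too short")
  at <- lines[3:(2 + n)]
  parse_num <- function(s, what, lineno) {
    v <- suppressWarnings(as.numeric(s))
    bad <- which(is.na(v))
    if (length(bad))
      stop("malformed GRO file at line ", lineno[bad[1]], ": bad ", what)
    v
  }
  lineno <- 3:(2 + n)
  beads <- data.frame(
    bead_id = seq_len(n),
    name = trimws(substr(at, 11, 15)),
    residue_id = as.integer(parse_num(substr(at, 1, 5), "residue id", lineno)),
    residue_name = trimws(substr(at, 6, 10)),
    molecule_id = NA_integer_,
    species = NA_character_,
    roles = "",
    vdw_radius_A = NA_real_,
    stringsAsFactors = FALSE)
  pos <- cbind(parse_num(substr(at, 21, 28), "x", lineno),
               parse_num(substr(at, 29, 36), "y", lineno),
               parse_num(substr(at, 37, 44), "z", lineno))
  box <- suppressWarnings(as.numeric(strsplit(trimws(lines[3 + n]),
                                              "\\s+")[[1]]))[1:3]
  if (any(is.na(box)))
    stop("malformed GRO file at line ", 3 + n, ": bad box line")
  list(beads = beads, positions = pos, box = box)
}

#' Write a system (with reference positions) as a GRO file
#' @param system a \code{membrane_system} carrying \code{$positions}.
#' @param path output path.
#' @param positions optional n_beads x 3 matrix (nm) overriding
#'   \code{system$positions}.
#' @export
write_gro <- function(system, path, positions = system$positions) {
  positions <- as_coord_matrix(positions, nrow(system$beads))
  b <- system$beads
  lines <- c("membrane system", format(nrow(b)),
             sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     b$residue_id %% 100000L, substr(b$residue_name, 1, 5),
                     substr(b$name, 1, 5), b$bead_id %% 100000L,
                     positions[, 1], positions[, 2], positions[, 3]),
             sprintf("%10.5f%10.5f%10.5f", system$box[1], system$box[2],
                     system$box[3]))
  writeLines(lines, path)
  invisible(path)
}

# --- PDB dialect (Angstrom -> nm), via bio3d -------------------------------

read_pdb_nm <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("reading PDB files requires the bio3d package")
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  n <- nrow(a)
  beads <- data.frame(
    bead_id = seq_len(n),
    name = trimws(a$elety),
    residue_id = as.integer(a$resno),
    residue_name = trimws(a$resid),
    molecule_id = NA_integer_,
    species = NA_character_,
    roles = "",
    vdw_radius_A = NA_real_,
    stringsAsFactors = FALSE)
  pos <- cbind(a$x, a$y, a$z) / 10  # A -> nm
  box <- tryCatch(pdb$cryst1$dims[1:3] / 10, error = function(e) NULL)
  if (is.null(box) || any(!is.finite(box)) || any(box <= 0)) {
    box <- apply(pos, 2, function(v) diff(range(v))) + 2
    warning("PDB file has no usable CRYST1 record; using bounding box + 2 nm")
  }
  list(beads = beads, positions = pos, box = box)
}

# --- Text trajectory fallback ----------------------------------------------
# Header "NBEADS <n>"; per frame a line "FRAME t Lx Ly Lz" followed by n
# lines "bead_id x y z" (nm).

#' Write a trajectory in the plain-text fallback format
#' @param traj a \code{membrane_trajectory}.
#' @param path output path.
#' @param digits significant digits for coordinates (>= 6).
#' @export
write_trajectory_text <- function(traj, path, digits = 8) {
  stopifnot(digits >= 6)
  nb <- dim(traj$coords)[1]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("NBEADS", nb), con)
  fmt <- paste0("%.", digits, "g")
  for (f in seq_len(n_frames(traj))) {
    writeLines(paste("FRAME", sprintf(fmt, traj$times[f]),
                     paste(sprintf(fmt, traj$box[f, ]), collapse = " ")), con)
    m <- traj$coords[, , f]
    writeLines(paste(seq_len(nb), sprintf(fmt, m[, 1]), sprintf(fmt, m[, 2]),
                     sprintf(fmt, m[, 3])), con)
  }
  invisible(path)
}

#' Load a trajectory
#'
#' Reads the plain-text fallback trajectory format. Compressed binary formats
#' (XTC/TRR/DCD) have no reader in this package; convert to the text fallback
#' first.
#'
#' @param path trajectory file path.
#' @param system the \code{membrane_system} the trajectory belongs to; frame
#'   atom counts are checked against its bead count.
#' @return a \code{membrane_trajectory} (times in ns). A single-frame
#'   trajectory is valid; its \code{interval} is \code{NA}.
#' @export
load_trajectory <- function(path, system) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xtc", "trr", "dcd"))
    stop("no reader available for .", ext,
         " in this environment; use the text fallback format")
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "NBEADS"))
    stop("malformed trajectory at line 1: expected 'NBEADS <n>'")
  nb <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]][2])
  if (is.na(nb)) stop("malformed trajectory at line 1: bad bead count")
  if (nb != nrow(system$beads))
    stop("trajectory has ", nb, " beads per frame but the system has ",
         nrow(system$beads))
  body <- lines[-1]
  is_frame <- startsWith(body, "FRAME")
  starts <- which(is_frame)
  if (!length(starts)) stop("trajectory contains no frames")
  ends <- c(starts[-1] - 1L, length(body))
  if (any(ends - starts != nb))
    stop("frame at line ", 1 + starts[which(ends - starts != nb)[1]],
         " does not contain exactly ", nb, " bead lines")
  nf <- length(starts)
  times <- numeric(nf)
  boxes <- matrix(0, nf, 3)
  coords <- array(NA_real_, c(nb, 3, nf))
  for (f in seq_len(nf)) {
    hdr <- as.numeric(strsplit(trimws(body[starts[f]]), "\\s+")[[1]][-1])
    if (length(hdr) != 4 || any(is.na(hdr)))
      stop("malformed trajectory at line ", 1 + starts[f],
           ": expected 'FRAME t Lx Ly Lz'")
    times[f] <- hdr[1]
    boxes[f, ] <- hdr[2:4]
    block <- body[(starts[f] + 1L):ends[f]]
    m <- matrix(scan(text = block, quiet = TRUE), ncol = 4, byrow = TRUE)
    coords[m[, 1], , f] <- m[, 2:4]
  }
  if (is.unsorted(times, strictly = TRUE))
    stop("non-monotonic frame times in trajectory")
  membrane_trajectory(times, coords, boxes)
}
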