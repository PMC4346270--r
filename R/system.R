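#' @keywords internal
"_PACKAGE"

SPECIES_LEVELS <- c("PROTEIN", "POPE", "POPG", "CL", "POPC", "ION", "SOLVENT")
ROLE_LEVELS <- c("HEADGROUP", "BACKBONE_CA", "TAIL")
LIPID_SPECIES <- c("POPE", "POPG", "CL", "POPC")

#' Construct an annotated membrane system
#'
#' A membrane system is the static description every analysis runs against:
#' a bead table (one row per particle, coarse-grained or atomistic) plus the
#' periodic box. Species tags separate protein, the lipid types and
#' solvent/ions; role tags mark head-group beads (used for lipid contacts,
#' leaflet assignment and density maps) and protein backbone beads (used for
#' superposition).
#'
#' @param beads data.frame with columns \code{bead_id} (unique integers),
#'   \code{name}, \code{residue_id} (1-based, taken verbatim from the input
#'   structure), \code{residue_name}, \code{molecule_id}, \code{species} (one
#'   of PROTEIN, POPE, POPG, CL, POPC, ION, SOLVENT), \code{roles}
#'   (semicolon-joined subset of HEADGROUP, BACKBONE_CA, TAIL; may be ""),
#'   \code{vdw_radius_A} (van der Waals radius in Angstrom).
#' @param box numeric length-3, box edge lengths (Lx, Ly, Lz) in nm.
#' @return object of class \code{membrane_system}.
#' @export
membrane_system <- function(beads, box) {
  required <- c("bead_id", "name", "residue_id", "residue_name",
                "molecule_id", "species", "roles", "vdw_radius_A")
  missing_cols <- setdiff(required, names(beads))
  if (length(missing_cols))
    stop("beads is missing columns: ", paste(missing_cols, collapse = ", "))
  beads <- as.data.frame(beads)[required]
  if (anyDuplicated(beads$bead_id))
    stop("bead_ids must be unique")
  bad_sp <- setdiff(unique(beads$species), SPECIES_LEVELS)
  if (length(bad_sp))
    stop("unknown species: ", paste(bad_sp, collapse = ", "))
  box <- as.numeric(box)
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
    stop("box must be three positive lengths (nm)")
  obj <- structure(list(beads = beads, box = box), class = "membrane_system")
  validate_membrane_system(obj)
  obj
}

validate_membrane_system <- function(system) {
  beads <- system$beads
  lip <- beads[beads$species %in% LIPID_SPECIES, ]
  if (nrow(lip)) {
    hg <- tapply(bead_has_role(lip, "HEADGROUP"), lip$molecule_id, any)
    if (!all(hg))
      stop("every lipid molecule needs at least one HEADGROUP bead; missing for molecule(s) ",
           paste(utils::head(names(hg)[!hg], 5), collapse = ", "))
  }
  prot <- beads[beads$species == "PROTEIN", ]
  if (nrow(prot)) {
    nca <- tapply(bead_has_role(prot, "BACKBONE_CA"), prot$residue_id, sum)
    if (any(nca != 1L))
      stop("every PROTEIN residue needs exactly one BACKBONE_CA bead; violated at residue(s) ",
           paste(utils::head(names(nca)[nca != 1L], 5), collapse = ", "))
  }
  invisible(system)
}

#' @export
print.membrane_system <- function(x, ...) {
  tab <- table(x$beads$species)
  cat("membrane_system:", nrow(x$beads), "beads, box",
      paste(signif(x$box, 4), collapse = " x "), "nm\n")
  cat("  species:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# Role matching on the semicolon-joined roles column.
bead_has_role <- function(beads, role) {
  grepl(paste0("(^|;)", role, "(;|$)"), beads$roles)
}

headgroup_index <- function(system, species) {
  which(system$beads$species == species & bead_has_role(system$beads, "HEADGROUP"))
}

protein_ca_index <- function(system) {
  which(system$beads$species == "PROTEIN" &
          bead_has_role(system$beads, "BACKBONE_CA"))
}

lipid_molecule_ids <- function(system, species = LIPID_SPECIES) {
  unique(system$beads$molecule_id[system$beads$species %in% species])
}

#' Assign lipids to bilayer leaflets
#'
#' The bilayer midplane is the mean z of all lipid HEADGROUP beads in the
#' frame; each lipid molecule goes to the OUTER leaflet (greater z) when the
#' mean z of its head-group beads exceeds the midplane and to INNER otherwise.
#' A lipid whose head group sits exactly on the midplane is assigned by the
#' mean z of all its beads; a remaining tie goes to INNER.
#'
#' @param frame either a \code{n_beads x 3} coordinate matrix (nm) or a
#'   \code{membrane_trajectory} frame extracted with \code{\link{get_frame}}.
#' @param system a \code{membrane_system}.
#' @return list with \code{leaflet} (named character vector, names =
#'   lipid molecule_ids, values "INNER"/"OUTER") and \code{midplane_z} (nm).
#' @export
assign_leaflets <- function(frame, system) {
  pos <- as_coord_matrix(frame, nrow(system$beads))
  beads <- system$beads
  is_lip <- beads$species %in% LIPID_SPECIES
  if (!any(is_lip)) stop("no lipids in system")
  hg <- is_lip & bead_has_role(beads, "HEADGROUP")
  midplane <- mean(pos[hg, 3])
  hg_z <- tapply(pos[hg, 3], beads$molecule_id[hg], mean)
  mol_z <- tapply(pos[is_lip, 3], beads$molecule_id[is_lip], mean)
  mol_z <- mol_z[names(hg_z)]
  dz <- hg_z - midplane
  tie <- dz == 0
  dz[tie] <- (mol_z - midplane)[tie]
  leaflet <- stats::setNames(as.vector(ifelse(dz > 0, "OUTER", "INNER")),
                             names(hg_z))     # remaining exact tie -> INNER
  list(leaflet = leaflet, midplane_z = midplane)
}

as_coord_matrix <- function(frame, n_beads) {
  if (is.list(frame) && !is.null(frame$positions)) frame <- frame$positions
  frame <- as.matrix(frame)
  if (ncol(frame) != 3L)
    stop("frame must have 3 coordinate columns")
  if (!missing(n_beads) && nrow(frame) != n_beads)
    stop("frame has ", nrow(frame), " positions but the system has ",
         n_beads, " beads")
  if (any(!is.finite(frame))) stop("non-finite coordinates in frame")
  frame
}
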