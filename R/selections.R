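#' Default selection rules for the synthetic pseudo-system
#'
#' Atom selections are configured as residue-name/atom-name rules per named
#' role rather than hard-coded, so the same analysis runs on the synthetic
#' pseudo-system and on a CHARMM-named all-atom system by swapping the
#' config. Roles used by the pipeline:
#' \describe{
#'   \item{lipid_P}{phosphorus atoms of the phospholipid head groups (leaflet
#'     assignment, bilayer centre, thickness)}
#'   \item{amphiphile}{one particle per amphiphile (phospholipid or sterol);
#'     its per-leaflet count is the denominator of the area per lipid}
#'   \item{ca_marker}{C-alpha atoms; a residue number narrows to one atom}
#'   \item{hvr_motif}{backbone atoms of the 5-aa hypervariable-region motif
#'     (residues 180-184)}
#'   \item{far_group}{atoms of the farnesyl lipid anchor}
#'   \item{gtp_group}{atoms of the bound GTP nucleotide}
#' }
#'
#' @return nested list: `roles$<role>` with optional `resnames`, `names`,
#'   `resnums` character/integer vectors (a missing key means "any").
#' @seealso [read_selection_config()], [resolve_selection()]
#' @export
selection_defaults <- function() {
  list(roles = list(
    lipid_P    = list(resnames = "DOP", names = "P"),
    amphiphile = list(resnames = c("DOP", "CHL")),
    ca_marker  = list(names = "CA"),
    hvr_motif  = list(resnums = 180:184, names = c("N", "CA", "C", "O")),
    far_group  = list(resnames = "FAR"),
    gtp_group  = list(resnames = "GTP")
  ))
}

#' Read a selection config from YAML
#'
#' The file mirrors the structure of [selection_defaults()]:
#' ```yaml
#' roles:
#'   lipid_P: {resnames: [DOPC, DOPS], names: [P]}
#'   ca_marker: {names: [CA]}
#' ```
#' @param path YAML file
#' @return selection config list
#' @export
read_selection_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$roles)) stop("selection config must have a 'roles' key")
  cfg
}

#' Resolve a named selection role to atom indices
#'
#' Pure function of the atom table and the rule: repeated resolution returns
#' identical, sorted (file-order) atom row indices.
#'
#' @param traj a [memtraj] (or anything with an `$atoms` table)
#' @param role role name present in `config$roles`
#' @param config selection config, default [selection_defaults()]
#' @param residue optional residue number to narrow the role (used with
#'   `ca_marker`); when given, exactly one atom must match
#' @return integer vector of atom row indices (1-based, increasing)
#' @export
resolve_selection <- function(traj, role, config = selection_defaults(),
                              residue = NULL) {
  rule <- config$roles[[role]]
  if (is.null(rule))
    stop("selection error: role '", role, "' not present in config")
  a <- traj$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(rule$resnames)) keep <- keep & a$resname %in% rule$resnames
  if (!is.null(rule$names))    keep <- keep & a$name %in% rule$names
  if (!is.null(rule$resnums))  keep <- keep & a$resno %in% rule$resnums
  if (!is.null(residue))       keep <- keep & a$resno == residue
  idx <- which(keep)
  if (!length(idx))
    stop("selection error: role '", role, "'",
         if (!is.null(residue)) paste0(" (residue ", residue, ")") else "",
         " matched no atoms")
  if (!is.null(residue) && length(idx) != 1L)
    stop("selection error: role '", role, "' residue ", residue,
         " matched ", length(idx), " atoms, expected exactly 1")
  idx
}
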