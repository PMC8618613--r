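# role maps: (residue name, atom name) -> semantic role + mass

#' Closed set of atom roles understood by the analyses
#'
#' @format Character vector of the valid roles.
#' @export
monolayer_roles <- c("aglycone_base", "aglycone_tip", "donor", "acceptor",
                     "hydrogen", "water_O", "water_H", "other")

#' Construct a role map
#'
#' A role map assigns a semantic role and a mass to every (residue name,
#' atom name) pair occurring in a coordinate file.  The mapping must be a
#' function: duplicate (residue, atom) keys are refused.
#'
#' @param entries data.frame with columns `residue`, `atom`, `role`, `mass`.
#' @return An object of class `rolemap`.
#' @seealso [default_rolemap()], [read_rolemap()]
#' @export
rolemap <- function(entries) {
  need <- c("residue", "atom", "role", "mass")
  if (!is.data.frame(entries) || !all(need %in% names(entries)))
    .stopf("rolemap entries need columns: %s", paste(need, collapse = ", "))
  entries <- entries[, need]
  entries$residue <- as.character(entries$residue)
  entries$atom <- as.character(entries$atom)
  entries$role <- as.character(entries$role)
  entries$mass <- as.numeric(entries$mass)
  bad <- setdiff(unique(entries$role), monolayer_roles)
  if (length(bad))
    .stopf("unknown role(s): %s", paste(bad, collapse = ", "))
  key <- paste(entries$residue, entries$atom, sep = "|")
  if (anyDuplicated(key))
    .stopf("duplicate rolemap key(s): %s",
           paste(unique(key[duplicated(key)]), collapse = ", "))
  if (any(!is.finite(entries$mass) | entries$mass < 0))
    .stopf("rolemap masses must be finite and non-negative")
  structure(list(entries = entries, key = key), class = "rolemap")
}

#' Read a role map from a YAML config file
#'
#' Expected layout:
#' ```yaml
#' roles:
#'   - {residue: ESC, atom: BAS, role: aglycone_base, mass: 12.011}
#'   - {residue: W,   atom: W,   role: water_O,       mass: 18.0154}
#' ```
#'
#' @param path path to the YAML file.
#' @return A `rolemap`.
#' @export
read_rolemap <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$roles)) .stopf("rolemap file has no 'roles' section: %s", path)
  rolemap(do.call(rbind, lapply(doc$roles, function(e)
    data.frame(residue = e$residue, atom = e$atom, role = e$role,
               mass = e$mass))))
}

#' Role map for the synthetic monolayer representation
#'
#' The synthetic surfactant (residue `ESC`) is a minimal proxy: an aglycone
#' base/tip atom pair defining the molecular axis, one donor with its
#' hydrogen, one acceptor, and five inert mass beads whose masses bring the
#' molecular mass to 1101 amu (escin).  Water is either a single 18-amu bead
#' (residue `W`) or a 3-site molecule (residue `SOL`).
#'
#' @return A `rolemap` covering the synthetic residues.
#' @export
default_rolemap <- function() {
  bead <- (1101.0 - (2 * 12.011 + 2 * 15.999 + 1.008)) / 5
  esc <- data.frame(
    residue = "ESC",
    atom = c("BAS", "TIP", "DON", "HD1", "ACC", paste0("M", 1:5)),
    role = c("aglycone_base", "aglycone_tip", "donor", "hydrogen",
             "acceptor", rep("other", 5)),
    mass = c(12.011, 12.011, 15.999, 1.008, 15.999, rep(bead, 5)))
  wat <- data.frame(
    residue = c("W", "SOL", "SOL", "SOL"),
    atom = c("W", "OW", "HW1", "HW2"),
    role = c("water_O", "water_O", "water_H", "water_H"),
    mass = c(18.0154, 15.999, 1.008, 1.008))
  rolemap(rbind(esc, wat))
}

# crude element mass guess for atoms outside the map (fallback mode)
.element_mass <- function(name) {
  el <- toupper(substr(gsub("^[0-9]+", "", name), 1L, 1L))
  m <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
         P = 30.974)
  ifelse(el %in% names(m), m[el], 0)
}

#' Assign roles and masses to atoms via a role map
#'
#' @param resname,name character vectors of residue and atom names.
#' @param map a [rolemap()].
#' @param fallback if `TRUE`, atoms absent from the map get role `"other"`
#'   and a mass guessed from the leading element letter; if `FALSE`, an
#'   unmapped atom is an error.
#' @return data.frame with columns `role`, `mass`.
#' @export
assign_roles <- function(resname, name, map = default_rolemap(),
                         fallback = TRUE) {
  stopifnot(inherits(map, "rolemap"))
  key <- paste(resname, name, sep = "|")
  i <- match(key, map$key)
  if (anyNA(i) && !fallback) {
    miss <- unique(key[is.na(i)])
    .stopf("role error: unmapped atom(s) with fallback disabled: %s",
           paste(head(miss, 5L), collapse = ", "))
  }
  role <- map$entries$role[i]
  mass <- map$entries$mass[i]
  if (anyNA(i)) {
    role[is.na(i)] <- "other"
    mass[is.na(i)] <- .element_mass(name[is.na(i)])
  }
  data.frame(role = role, mass = mass)
}
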