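# the central container: one time point of an annotated monolayer system

#' Construct a monolayer frame
#'
#' One time point of atom coordinates with semantic roles, masses, molecule
#' ids and the periodic box.  Internal units: nm, ns, amu.
#'
#' @param atoms data.frame with columns `id`, `mol`, `resname`, `name`,
#'   `role`, `mass`, `x`, `y`, `z`.
#' @param box numeric length-3, box lengths `(Lx, Ly, Lz)` in nm.
#' @param time frame time in ns.
#' @param validate run the invariant checks (finite coordinates, positive
#'   box, closed role set, exactly one aglycone base and tip per surfactant
#'   molecule).
#' @return Object of class `monolayer_frame`: a list with `atoms`, `box`,
#'   `time`.
#' @export
monolayer_frame <- function(atoms, box, time = 0, validate = TRUE) {
  need <- c("id", "mol", "resname", "name", "role", "mass", "x", "y", "z")
  if (!is.data.frame(atoms) || !all(need %in% names(atoms)))
    .stopf("atoms need columns: %s", paste(need, collapse = ", "))
  atoms <- atoms[, need]
  box <- as.numeric(box)
  fr <- structure(list(atoms = atoms, box = box, time = as.numeric(time)),
                  class = "monolayer_frame")
  if (validate) validate_frame(fr)
  fr
}

#' Check the invariants of a monolayer frame
#'
#' @param frame a [monolayer_frame()].
#' @return The frame, invisibly; stops on violation.
#' @export
validate_frame <- function(frame) {
  stopifnot(inherits(frame, "monolayer_frame"))
  a <- frame$atoms
  if (length(frame$box) != 3L || any(!is.finite(frame$box)) ||
      any(frame$box <= 0))
    .stopf("box must be three positive finite lengths (nm)")
  if (any(!is.finite(c(a$x, a$y, a$z))))
    .stopf("non-finite coordinates in frame")
  bad <- setdiff(unique(a$role), monolayer_roles)
  if (length(bad))
    .stopf("unknown role(s) in frame: %s", paste(bad, collapse = ", "))
  # every surfactant molecule carries exactly one base and one tip atom
  surf <- unique(a$mol[a$role %in% c("aglycone_base", "aglycone_tip")])
  if (length(surf)) {
    nb <- table(factor(a$mol[a$role == "aglycone_base"], levels = surf))
    nt <- table(factor(a$mol[a$role == "aglycone_tip"], levels = surf))
    if (any(nb != 1L) || any(nt != 1L))
      .stopf("each surfactant molecule must have exactly one aglycone base and one tip atom")
  }
  invisible(frame)
}

#' @export
print.monolayer_frame <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("monolayer_frame: %d atoms, %d molecules, t = %g ns\n",
              nrow(a), length(unique(a$mol)), x$time))
  cat(sprintf("  box: %.3f x %.3f x %.3f nm\n",
              x$box[1], x$box[2], x$box[3]))
  tab <- table(a$role)
  cat("  roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
      "\n")
  invisible(x)
}

#' Classify molecules of a frame by type
#'
#' A molecule is a `surfactant` if it carries an aglycone base atom, `water`
#' if it carries a water oxygen, otherwise `other`.
#'
#' @param frame a [monolayer_frame()].
#' @return Named character vector keyed by molecule id.
#' @export
molecule_types <- function(frame) {
  a <- frame$atoms
  mols <- sort(unique(a$mol))
  type <- rep("other", length(mols))
  type[mols %in% a$mol[a$role == "aglycone_base"]] <- "surfactant"
  type[mols %in% a$mol[a$role == "water_O"]] <- "water"
  setNames(type, mols)
}

# base/tip coordinate matrices ordered by molecule id, for surfactants
.axis_atoms <- function(frame) {
  a <- frame$atoms
  b <- a[a$role == "aglycone_base", ]
  t <- a[a$role == "aglycone_tip", ]
  b <- b[order(b$mol), ]
  t <- t[order(t$mol), ]
  if (nrow(b) == 0L) .stopf("frame has no surfactant molecules")
  if (!identical(b$mol, t$mol))
    .stopf("mismatched aglycone base/tip molecules")
  list(mol = b$mol,
       base = cbind(b$x, b$y, b$z),
       tip = cbind(t$x, t$y, t$z))
}
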