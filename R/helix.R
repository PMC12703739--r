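# Eisenberg consensus hydrophobicity scale.
EISENBERG <- c(
  A = 0.62, R = -2.53, N = -0.78, D = -0.90, C = 0.29,
  Q = -0.85, E = -0.74, G = 0.48, H = -0.40, I = 1.38,
  L = 1.06, K = -1.50, M = 0.64, F = 1.19, P = 0.12,
  S = -0.18, T = -0.05, W = 0.81, Y = 0.26, V = 1.08
)

#' Ideal alpha-helix parameters
#'
#' Standard alpha-helix geometry: 1.5 Angstrom rise per residue, 100
#' degrees twist per residue (3.6 residues/turn) and a 2.3 Angstrom
#' C-alpha helix radius.
#'
#' @param rise_per_residue Rise along the axis per residue (Angstrom).
#' @param twist Rotation about the axis per residue (degrees).
#' @param radius C-alpha distance from the axis (Angstrom).
#' @return One-row tibble of parameters.
#' @export
helix_params <- function(rise_per_residue = 1.5, twist = 100, radius = 2.3) {
  if (rise_per_residue <= 0 || twist <= 0 || radius <= 0) {
    abort("helix parameters must be positive")
  }
  tibble(rise_per_residue = rise_per_residue, twist = twist, radius = radius)
}

#' Helical-wheel projection of a sequence
#'
#' Projects residues onto the plane perpendicular to an ideal helix axis:
#' residue i sits at angle `(i - 1) * twist mod 360`. Hydrophobicity uses
#' the Eisenberg consensus scale, the standard choice for moment
#' calculations; masks designed to pack an apolar face against the binder
#' show the classic amphipathic segregation on this wheel.
#'
#' @param seq One-letter sequence (non-empty).
#' @param twist Degrees per residue (default 100).
#' @return Tibble of class `afm_wheel`: `position`, `residue`,
#'   `angle_deg`, `hydrophobicity`.
#' @export
helical_wheel <- function(seq, twist = 100) {
  if (!is.character(seq) || length(seq) != 1 || !nzchar(seq)) abort("empty sequence")
  chars <- strsplit(seq, "")[[1]]
  if (any(!chars %in% names(EISENBERG))) {
    abort(paste0("unknown residue(s): ",
                 paste(unique(chars[!chars %in% names(EISENBERG)]), collapse = ", ")))
  }
  out <- tibble(
    position = seq_along(chars),
    residue = chars,
    angle_deg = ((seq_along(chars) - 1) * twist) %% 360,
    hydrophobicity = unname(EISENBERG[chars])
  )
  class(out) <- c("afm_wheel", class(out))
  out
}

#' Mean hydrophobic moment of a helical sequence
#'
#' Magnitude of the vector sum of per-residue hydrophobicities around the
#' helical wheel, divided by the number of residues, so sequences of
#' different length are comparable. High values indicate an amphipathic
#' helix (apolar and polar faces segregated).
#'
#' @param seq One-letter sequence, length >= 2.
#' @param twist Degrees per residue (default 100).
#' @return Mean hydrophobic moment (scalar, scale units per residue).
#' @export
hydrophobic_moment <- function(seq, twist = 100) {
  if (!is.character(seq) || length(seq) != 1 || nchar(seq) < 2) {
    abort("sequence must have at least 2 residues")
  }
  w <- helical_wheel(seq, twist)
  theta <- w$angle_deg * pi / 180
  mx <- sum(w$hydrophobicity * cos(theta))
  my <- sum(w$hydrophobicity * sin(theta))
  sqrt(mx^2 + my^2) / nrow(w)
}

#' Generate an ideal helix as a C-alpha trace
#'
#' Places C-alpha atoms on a perfect helix of the given radius, rise and
#' twist about an arbitrary axis. The consecutive C-alpha distance follows
#' the closed form `sqrt(rise^2 + (2 r sin(twist/2))^2)` (3.83 Angstrom
#' with default parameters). Used to build synthetic helix-bundle
#' fixtures.
#'
#' @param n Number of residues (>= 2).
#' @param params [helix_params()] row.
#' @param axis_origin Position of the first residue's axis point
#'   (3-vector, Angstrom).
#' @param axis_direction Helix axis direction (3-vector, normalised
#'   internally; must be non-zero).
#' @param phase Angular phase of the first residue (degrees).
#' @param chain Chain id for the emitted structure.
#' @param sequence Optional one-letter sequence of length `n` (defaults
#'   to poly-alanine) setting residue names.
#' @param reverse_numbering If `TRUE`, residue indices run against the
#'   axis direction (geometric C-to-N layout), used to control terminal
#'   placement in fixtures.
#' @return An [afm_structure()] with one CA-only chain.
#' @export
make_ideal_helix <- function(n, params = helix_params(),
                             axis_origin = c(0, 0, 0),
                             axis_direction = c(0, 0, 1),
                             phase = 0, chain = "A", sequence = NULL,
                             reverse_numbering = FALSE) {
  if (n < 2) abort("need at least 2 residues")
  nrm <- sqrt(sum(axis_direction^2))
  if (nrm == 0) abort("zero axis direction vector")
  u <- axis_direction / nrm
  i <- seq_len(n) - 1
  theta <- (phase + i * params$twist) * pi / 180
  local <- cbind(params$radius * cos(theta),
                 params$radius * sin(theta),
                 i * params$rise_per_residue)
  # rotate local z onto u with a minimal rotation
  rot <- rotation_from_z(u)
  coords <- local %*% t(rot)
  coords <- sweep(coords, 2, axis_origin, "+")
  if (is.null(sequence)) sequence <- strrep("A", n)
  if (nchar(sequence) != n) abort("sequence length must equal n")
  resnames <- AA_ONE_TO_THREE[strsplit(sequence, "")[[1]]]
  if (any(is.na(resnames))) abort("sequence contains a non-standard residue")
  ord <- if (reverse_numbering) rev(seq_len(n)) else seq_len(n)
  afm_structure(
    tibble(
      chain = chain,
      resno = seq_len(n),
      resname = unname(resnames),
      atom = "CA",
      element = "C",
      x = coords[ord, 1], y = coords[ord, 2], z = coords[ord, 3]
    ),
    model_id = paste0("ideal_helix_", chain)
  )
}

# Minimal rotation taking the z axis onto unit vector u.
rotation_from_z <- function(u) {
  z <- c(0, 0, 1)
  c_ <- sum(z * u)
  if (abs(c_ - 1) < 1e-12) return(diag(3))
  if (abs(c_ + 1) < 1e-12) return(diag(c(1, -1, -1)))
  v <- c(z[2] * u[3] - z[3] * u[2], z[3] * u[1] - z[1] * u[3], z[1] * u[2] - z[2] * u[1])
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c_)
}
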