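# Built-in binding-group table. R4-1 and R6-1 carry measured radii; the
# radii of the remaining groups and the theoretical charges of R3-1 and R6-1
# are model defaults (never used by the headline sweeps, always overridable).
.binding_group_table <- data.frame(
  name = c("R1-1", "R3-1", "R4-1", "R4-2", "R6-1"),
  theoretical_charge = c(1, 2, 3, 3, 4),
  group_radius = c(3.5, 5.5, 6.61, 7.0, 7.10),
  stringsAsFactors = FALSE
)

#' Cationic binding-group specification
#'
#' The oligoamine binding groups grafted on the polymer surface, named by
#' their nitrogen count and linker variant (R1-1, R3-1, R4-1, R4-2, R6-1).
#' Each carries a theoretical protonation charge, an effective charge (the
#' charge presented in solution after shielding; defaults to the theoretical
#' value and is freely configurable since it is generally not known), and a
#' group radius in Angstrom. Built-in constants: R4-1 has theoretical charge
#' +3 and radius 6.61 A; R6-1 has radius 7.10 A.
#'
#' @param name One of `"R1-1"`, `"R3-1"`, `"R4-1"`, `"R4-2"`, `"R6-1"`.
#' @param effective_charge Effective charge in elementary units; default is
#'   the group's theoretical charge.
#' @param theoretical_charge,group_radius Overrides for the built-in values.
#' @return An object of class `binding_group`.
#' @export
#' @examples
#' binding_group("R4-1")
#' binding_group("R6-1", effective_charge = 3)
binding_group <- function(name = "R4-1", effective_charge = NULL,
                          theoretical_charge = NULL, group_radius = NULL) {
  row <- .binding_group_table[.binding_group_table$name == name, ]
  if (nrow(row) == 0)
    stop("binding_group: unknown group '", name, "'; known groups: ",
         paste(.binding_group_table$name, collapse = ", "), call. = FALSE)
  theo <- if (is.null(theoretical_charge)) row$theoretical_charge else theoretical_charge
  eff <- if (is.null(effective_charge)) theo else effective_charge
  rad <- if (is.null(group_radius)) row$group_radius else group_radius
  if (eff <= 0)
    stop("binding_group: effective charge must be positive for a usable group",
         call. = FALSE)
  if (rad <= 0)
    stop("binding_group: group radius must be positive", call. = FALSE)
  structure(list(name = name, theoretical_charge = theo,
                 effective_charge = eff, group_radius = rad),
            class = "binding_group")
}

#' @export
print.binding_group <- function(x, ...) {
  cat(sprintf("binding_group %s: theoretical %+g e, effective %+g e, radius %g A\n",
              x$name, x$theoretical_charge, x$effective_charge, x$group_radius))
  invisible(x)
}
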