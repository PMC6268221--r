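#' The nine classification tasks and their class alphabets
#'
#' Structure elucidation from unassigned shifts is posed as nine independent
#' classification tasks: the anomeric configurations of the first glycosidic
#' linkage (`ano_f`), the second linkage (`ano_s`) and the reducing end
#' (`ano_r`); the first and second linkage positions (`f_link`, `s_link`);
#' the identities of the reducing-end, middle and first residues (`red_end`,
#' `m_residue`, `f_residue`); and the chain type (`chain_type`).
#'
#' Class codes are single letters: for anomers A = \eqn{\alpha}, B =
#' \eqn{\beta}; for linkages A = 1\eqn{\to}2, B = 1\eqn{\to}3, C = 1\eqn{\to}4,
#' D = 1\eqn{\to}6; for residues A = Glc, B = Gal, C = Man, D = Rha, E = Fuc;
#' for chain type A = linear, B = branched. Tasks that do not apply to
#' disaccharides (`ano_s`, `f_link`, `m_residue`, `chain_type`) carry the
#' extra class X ("not applicable").
#'
#' @return `glyco_tasks()` returns a named list mapping each task name to its
#'   class alphabet (a character vector).
#' @examples
#' glyco_tasks()$s_link
#' @export
glyco_tasks <- function() {
  list(
    ano_f      = c("A", "B"),
    ano_s      = c("A", "B", "X"),
    ano_r      = c("A", "B"),
    f_link     = c("A", "B", "C", "D", "X"),
    s_link     = c("A", "B", "C", "D"),
    red_end    = c("A", "B", "C", "D", "E"),
    m_residue  = c("A", "B", "C", "D", "E", "X"),
    f_residue  = c("A", "B", "C", "D", "E"),
    chain_type = c("A", "B", "X")
  )
}

#' @rdname glyco_tasks
#' @return `task_names()` returns the nine task names in canonical order.
#' @export
task_names <- function() names(glyco_tasks())

monomers <- c("Glc", "Gal", "Man", "Rha", "Fuc")
deoxy_monomers <- c("Rha", "Fuc")
linkage_positions <- c(2L, 3L, 4L, 6L)

monomer_class <- function(m) c(Glc = "A", Gal = "B", Man = "C", Rha = "D", Fuc = "E")[[m]]
linkage_class <- function(p) c(`2` = "A", `3` = "B", `4` = "C", `6` = "D")[[as.character(p)]]
anomer_class <- function(a) c(alpha = "A", beta = "B")[[a]]
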