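#' Computer-science doctorates vs arcade revenue, 2000-2009
#'
#' A 10-row example dataset: computer science doctorates awarded in the US
#' and total revenue generated by arcades (billions of USD) for the years
#' 2000-2009.  The two series are strongly monotonically associated
#' (tau = 0.822) despite having no plausible causal link, which makes the
#' dataset a compact worked example for rank-correlation inference.  The
#' same rows ship as a CSV at
#' `system.file("extdata", "arcade.csv", package = "taufast")` for the
#' command-line interface.
#'
#' @return A data frame with columns `year`, `doctorates`, `revenue`.
#' @examples
#' arcade_data()
#' @export
arcade_data <- function() {
  data.frame(
    year = 2000:2009,
    doctorates = c(861, 830, 809, 867, 948, 1129, 1453, 1656, 1787, 1611),
    revenue = c(1.196, 1.176, 1.269, 1.240, 1.307, 1.435, 1.601, 1.654,
                1.803, 1.734)
  )
}
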