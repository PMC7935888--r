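#' Simulate a circadian expression time course with known ground truth
#'
#' Generates a genes x timepoints matrix of FPKM-like abundances with a
#' cosinor mean structure and multiplicative log-normal noise:
#' \deqn{x_{gt} = B_g (1 + A_g \cos(2\pi (t - \phi_g)/24)) e^{\epsilon},
#'   \quad \epsilon \sim N(0, \sigma^2)}
#' Each gene is assigned a phase class: DAY genes draw their acrophase
#' \eqn{\phi} from [0, 12), NIGHT genes from [12, 24), and ARRHYTHMIC genes
#' have amplitude 0. The generative period is fixed at 24 h (entrained
#' conditions).
#'
#' @param n_genes number of genes (>= 1).
#' @param timepoints strictly increasing sampling times in hours; the study
#'   design this emulates samples every 3 h over 24 h.
#' @param class_fractions named numeric vector over
#'   \code{c("DAY","NIGHT","ARRHYTHMIC")} summing to 1. Defaults mirror the
#'   observed 142/57/21 partition of expressed detoxification genes.
#' @param amplitude_range range of relative amplitudes A for rhythmic genes.
#' @param baseline_range range of baselines B (uniform on log10 scale).
#' @param noise_sd standard deviation of the log-normal noise term.
#' @param acrophase_grid optional spacing (h); when given, acrophases are
#'   drawn from the grid \code{seq(0, 24 - grid, by = grid)} restricted to
#'   the class window, rather than uniformly.
#' @param seed integer seed; fully determines the output.
#' @return list with \code{matrix} (genes x timepoints, dimnames gene ids and
#'   \code{"ZT<h>"} labels), \code{timepoints}, and \code{truth}, a
#'   data.frame with columns gene_id, class, baseline, amplitude,
#'   acrophase_hours, noise_sd.
#' @examples
#' sim <- simulate_expression(20, seq(0, 21, by = 3), seed = 1)
#' head(sim$truth)
#' @export
simulate_expression <- function(n_genes,
                                timepoints = seq(0, 21, by = 3),
                                class_fractions = c(DAY = 0.645, NIGHT = 0.259,
                                                    ARRHYTHMIC = 0.096),
                                amplitude_range = c(0.3, 0.9),
                                baseline_range = c(1, 1000),
                                noise_sd = 0.2,
                                acrophase_grid = NULL,
                                seed = 1L) {
  .assert(n_genes >= 1, "n_genes must be >= 1")
  .assert(length(timepoints) >= 1, "timepoints must be non-empty")
  .assert(all(diff(timepoints) > 0), "timepoints must be strictly increasing")
  .assert(length(class_fractions) == 3 &&
            setequal(names(class_fractions), c("DAY", "NIGHT", "ARRHYTHMIC")),
          "class_fractions must be named over DAY/NIGHT/ARRHYTHMIC")
  .assert(all(class_fractions >= 0) && abs(sum(class_fractions) - 1) < 1e-8,
          "class_fractions must be a simplex (non-negative, sum 1)")
  .assert(noise_sd >= 0, "noise_sd must be >= 0")

  cf <- class_fractions[c("DAY", "NIGHT", "ARRHYTHMIC")]
  set.seed(as.integer(seed))
  cls <- sample(names(cf), n_genes, replace = TRUE, prob = cf)

  baseline <- 10^runif(n_genes, log10(baseline_range[1]), log10(baseline_range[2]))
  amp <- runif(n_genes, amplitude_range[1], amplitude_range[2])
  amp[cls == "ARRHYTHMIC"] <- 0

  draw_phase <- function(lo, hi, n) {
    if (is.null(acrophase_grid)) return(runif(n, lo, hi))
    grid <- seq(0, 24 - acrophase_grid, by = acrophase_grid)
    grid <- grid[grid >= lo & grid < hi]
    grid[sample.int(length(grid), n, replace = TRUE)]
  }
  phi <- numeric(n_genes)
  phi[cls == "DAY"] <- draw_phase(0, 12, sum(cls == "DAY"))
  phi[cls == "NIGHT"] <- draw_phase(12, 24, sum(cls == "NIGHT"))
  phi[cls == "ARRHYTHMIC"] <- 0

  # cosinor mean: B_g * (1 + A_g cos(2 pi (t - phi_g) / 24))
  ph <- outer(phi, timepoints, function(p, t) cos(2 * pi * (t - p) / 24))
  mean_mat <- baseline * (1 + amp * ph)
  eps <- matrix(rnorm(n_genes * length(timepoints), sd = noise_sd),
                nrow = n_genes)
  x <- mean_mat * exp(eps)

  ids <- sprintf("gene%04d", seq_len(n_genes))
  dimnames(x) <- list(ids, paste0("ZT", timepoints))
  truth <- data.frame(gene_id = ids, class = cls, baseline = baseline,
                      amplitude = amp, acrophase_hours = phi,
                      noise_sd = noise_sd, stringsAsFactors = FALSE)
  list(matrix = x, timepoints = timepoints, truth = truth, seed = as.integer(seed))
}

#' Write / read an expression matrix as TSV with ZT/CT column labels
#'
#' @param x genes x timepoints matrix with \code{"ZT<h>"} / \code{"CT<h>"}
#'   column names (optional \code{".rep<k>"} suffix for replicates).
#' @param path output file.
#' @return \code{write_expression_tsv}: the path, invisibly.
#'   \code{read_expression_tsv}: list with \code{matrix}, \code{timepoints}
#'   (hours parsed from the labels) and \code{condition} ("LD" for ZT labels,
#'   "DD" for CT).
#' @export
write_expression_tsv <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  .assert("gene_id" %in% names(df), "expression TSV must have a gene_id column")
  m <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  rownames(m) <- df$gene_id
  lab <- colnames(m)
  ok <- grepl("^(ZT|CT)[0-9]+(\\.[0-9]+)?(\\.rep[0-9]+)?$", lab)
  .assert(all(ok), "columns must be labelled ZT<h> or CT<h> (optional .rep<k>)")
  hours <- as.numeric(sub("\\.rep[0-9]+$", "", sub("^(ZT|CT)", "", lab)))
  cond <- if (all(startsWith(lab, "CT"))) "DD" else "LD"
  list(matrix = m, timepoints = hours, condition = cond)
}
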