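# Config-driven pipeline: runs any subset of analysis stages on input
# files (or freshly generated synthetic inputs) and writes per-stage
# report tables plus a run log.

#' Build a pipeline configuration
#'
#' All numeric defaults of the analysis (fluorophore lifetime, orientation
#' factor, refractive index, quantum yield, diffusion limit) live here, not
#' in the stage code, and every adopted value is echoed in the run log.
#'
#' @param stages Character vector drawn from `"synth"`, `"quench"`,
#'   `"binding"`, `"thermo"`, `"fret"`, `"mst"`, `"cd"`, `"eem"`, `"ans"`.
#' @param out_dir Output directory for report tables and the run log.
#' @param inputs Named list of input file paths / values:
#'   `titration` (long-format table), `donor_spectrum`,
#'   `acceptor_absorbance`, `acceptor_conc_molar`, `J`, `efficiency`,
#'   `dose_response`, `cd_spectrum`, `eem`, `ans_reference`, `ans_treated`.
#' @param truth A [synthetic_truth()] used by the `"synth"` stage.
#' @param tau0 Fluorophore lifetime, s.
#' @param diffusion_limit Diffusion-collision limit, L/mol/s.
#' @param fret A [fret_constants()] object.
#' @param protein A [protein_constants()] object.
#' @param A_total Labeled-species concentration for the mst stage, mol/L.
#' @param seed Integer seed for the synth stage.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(stages, out_dir,
                       inputs = list(),
                       truth = synthetic_truth(),
                       tau0 = 1e-8,
                       diffusion_limit = 2.0e10,
                       fret = fret_constants(),
                       protein = protein_constants(),
                       A_total = 2e-7,
                       seed = 1L) {
  known <- c("synth", "quench", "binding", "thermo", "fret", "mst",
             "cd", "eem", "ans")
  bad <- setdiff(stages, known)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  structure(list(stages = stages, out_dir = out_dir, inputs = inputs,
                 truth = truth, tau0 = tau0,
                 diffusion_limit = diffusion_limit,
                 fret = fret, protein = protein, A_total = A_total,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map directly onto [run_config()] arguments; `fret`,
#' `protein` and `truth` may be given as nested maps of the corresponding
#' constructor arguments.
#'
#' @param path YAML file path.
#' @return A `"run_config"`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(
    stages = y$stages,
    out_dir = y$out_dir %||% ".",
    inputs = y$inputs %||% list(),
    truth = if (is.null(y$truth)) synthetic_truth()
            else do.call(synthetic_truth, y$truth),
    tau0 = y$tau0 %||% 1e-8,
    diffusion_limit = y$diffusion_limit %||% 2.0e10,
    fret = if (is.null(y$fret)) fret_constants()
           else do.call(fret_constants, y$fret),
    protein = if (is.null(y$protein)) protein_constants()
              else do.call(protein_constants, y$protein),
    A_total = y$A_total %||% 2e-7,
    seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order (synth, quench,
#' binding, thermo, fret, mst, cd, eem, ans).  `thermo` consumes the Ka
#' values fitted by `binding`; `quench`/`binding` read the titration table
#' named in the config inputs, or the one the `synth` stage just wrote.
#' Warnings never abort a run: they are collected, printed into the run
#' log, and attached to the result.
#'
#' @param config A [run_config()], or the path to a YAML file for
#'   [read_run_config()].
#' @return Invisibly, a list of class `"pipeline_run"` with one element
#'   per executed stage plus `warnings` and `log`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  order_ <- c("synth", "quench", "binding", "thermo", "fret", "mst",
              "cd", "eem", "ans")
  stages <- order_[order_ %in% config$stages]
  res <- list()
  warns <- character(0)
  log <- c(sprintf("stages: %s", paste(stages, collapse = ", ")),
           sprintf("seed: %d", config$seed),
           sprintf("tau0 [s]: %g", config$tau0),
           sprintf("diffusion limit [L/mol/s]: %g", config$diffusion_limit),
           sprintf("kappa^2: %g; refractive index: %g; quantum yield: %g",
                   config$fret$kappa2, config$fret$refractive_index,
                   config$fret$quantum_yield),
           sprintf("protein: M = %g g/mol, %d residues, CD path %g cm, %g g/L",
                   config$protein$molecular_weight,
                   config$protein$residue_count,
                   config$protein$cd_path_length_cm,
                   config$protein$concentration_g_per_L),
           sprintf("A_total [mol/L]: %g", config$A_total))
  collect <- function(expr, stage) {
    withCallingHandlers(
      tryCatch(expr, error = function(e)
        stop(sprintf("stage '%s': %s", stage, conditionMessage(e)),
             call. = FALSE)),
      warning = function(w) {
        warns <<- c(warns, sprintf("[%s] %s", stage, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }
  inp <- config$inputs
  out_path <- function(name) file.path(config$out_dir, name)

  for (stage in stages) {
    if (stage == "synth") {
      res$synth <- collect({
        truth <- config$truth
        # The emitted titrations emulate the observed Stern-Volmer
        # quenching (Ksv per temperature, single site); the double-log
        # constants are a reparameterization fitted downstream.
        truth_sv <- truth
        if (!is.null(truth$ksv_by_T)) truth_sv$n_sites <- 1
        series <- lapply(as.numeric(names(truth$ksv_by_T)), function(tt)
          gen_quench_titration(truth_sv, tt, seed = config$seed + tt))
        write_titration_table(series, out_path("synthetic_titration.csv"))
        mst <- gen_mst_curve(truth, A_total = config$A_total,
                             seed = config$seed)
        write_dose_response(mst$dose_molar, mst$response,
                            out_path("synthetic_dose_response.csv"))
        pair <- gen_spectra_pair(truth, seed = config$seed)
        write_spectrum(pair$emission, out_path("synthetic_emission.csv"))
        write_spectrum(pair$absorbance, out_path("synthetic_absorbance.csv"))
        write_eem(gen_eem(seed = config$seed),
                  out_path("synthetic_eem.csv"))
        ans_ref <- gen_ans_series(truth$s0[[1]],
                                  noise_sd_relative = truth$noise_sd_relative,
                                  seed = config$seed)
        ans_trt <- gen_ans_series(truth$s0[[length(truth$s0)]],
                                  noise_sd_relative = truth$noise_sd_relative,
                                  seed = config$seed + 1L)
        utils::write.csv(ans_ref, out_path("synthetic_ans_reference.csv"),
                         row.names = FALSE)
        utils::write.csv(ans_trt, out_path("synthetic_ans_treated.csv"),
                         row.names = FALSE)
        inp$titration <- inp$titration %||% out_path("synthetic_titration.csv")
        inp$dose_response <- inp$dose_response %||%
          out_path("synthetic_dose_response.csv")
        inp$donor_spectrum <- inp$donor_spectrum %||%
          out_path("synthetic_emission.csv")
        inp$acceptor_absorbance <- inp$acceptor_absorbance %||%
          out_path("synthetic_absorbance.csv")
        inp$acceptor_conc_molar <- inp$acceptor_conc_molar %||% 5e-6
        inp$eem <- inp$eem %||% out_path("synthetic_eem.csv")
        inp$ans_reference <- inp$ans_reference %||%
          out_path("synthetic_ans_reference.csv")
        inp$ans_treated <- inp$ans_treated %||%
          out_path("synthetic_ans_treated.csv")
        list(truth = truth)
      }, stage)
      log <- c(log, "synth: wrote synthetic inputs from ground truth")
    }

    if (stage %in% c("quench", "binding") && is.null(res$titration)) {
      if (is.null(inp$titration))
        stop(sprintf("stage '%s': no titration table (dependency: synth stage or inputs$titration)",
                     stage), call. = FALSE)
      res$titration <- collect(read_titration_table(inp$titration), stage)
    }

    if (stage == "quench") {
      res$quench <- collect(
        lapply(res$titration, stern_volmer_fit, tau0 = config$tau0), stage)
      res$mechanism <- collect(
        if (length(res$quench) >= 2)
          classify_mechanism(res$quench, config$diffusion_limit)
        else NULL, stage)
      tab <- quench_table(res$quench)
      utils::write.csv(tab, out_path("quench_table.csv"), row.names = FALSE)
      log <- c(log, sprintf("quench: %d series; mechanism: %s",
                            length(res$quench),
                            res$mechanism$mechanism %||% "n/a"))
    }

    if (stage == "binding") {
      res$binding <- collect(lapply(res$titration, double_log_fit), stage)
      tab <- data.frame(
        temperature_K = vapply(res$binding, `[[`, numeric(1), "temperature_K"),
        ka_L_per_mol = vapply(res$binding, `[[`, numeric(1), "ka"),
        n_sites = vapply(res$binding, `[[`, numeric(1), "n_sites"),
        r_squared = vapply(res$binding, `[[`, numeric(1), "r_squared"))
      utils::write.csv(tab, out_path("binding_table.csv"), row.names = FALSE)
      log <- c(log, sprintf("binding: %d series fitted", length(res$binding)))
    }

    if (stage == "thermo") {
      if (is.null(res$binding) && is.null(inp$ka_table))
        stop("stage 'thermo': no association constants (dependency: binding stage or inputs$ka_table)",
             call. = FALSE)
      res$thermo <- collect({
        if (!is.null(res$binding)) {
          temps <- vapply(res$binding, `[[`, numeric(1), "temperature_K")
          kas <- vapply(res$binding, `[[`, numeric(1), "ka")
        } else {
          m <- parse_numeric_table(inp$ka_table, 2L)
          temps <- m[, 1]; kas <- m[, 2]
        }
        vant_hoff_fit(temps, kas)
      }, stage)
      forces <- classify_forces(res$thermo$dH, res$thermo$dS)
      res$forces <- forces
      if (!is.null(res$binding)) {
        tab <- thermo_table(res$binding, res$thermo)
        utils::write.csv(tab, out_path("thermo_table.csv"), row.names = FALSE)
      }
      log <- c(log, sprintf(
        "thermo: dH = %.4g kJ/mol, dS = %.4g J/mol/K, force: %s%s",
        res$thermo$dH / 1000, res$thermo$dS, forces$force,
        if (!res$thermo$consistent) " (dG identity diagnostic flagged)" else ""))
    }

    if (stage == "fret") {
      res$fret <- collect({
        J <- inp$J
        if (is.null(J)) {
          if (is.null(inp$donor_spectrum) || is.null(inp$acceptor_absorbance) ||
              is.null(inp$acceptor_conc_molar))
            stop("need inputs$J or donor_spectrum + acceptor_absorbance + acceptor_conc_molar",
                 call. = FALSE)
          donor <- read_spectrum(inp$donor_spectrum, kind = "emission")
          acc <- read_spectrum(inp$acceptor_absorbance, kind = "absorbance")
          eps <- molar_absorptivity(acc, inp$acceptor_conc_molar)
          J <- overlap_integral(donor, eps)
        }
        r0 <- forster_radius(J, config$fret)
        E <- inp$efficiency
        prot <- inp$protein_conc_molar %||% 1e-6
        if (is.null(E) && !is.null(res$quench)) {
          # 1:1 ligand:protein convention, read off the fitted
          # Stern-Volmer line (robust to single-point noise).
          ksv <- res$quench[[1]]$ksv
          if (ksv > 0) E <- 1 - 1 / (1 + ksv * prot)
        }
        if (is.null(E) && !is.null(res$titration)) {
          # fall back to the raw titration point nearest 1:1
          s <- res$titration[[1]]
          i <- which.min(abs(s$conc_molar[-1] - prot)) + 1L
          E <- transfer_efficiency(s$intensity[i], s$intensity[1])
        }
        if (is.null(E))
          stop("need inputs$efficiency (or a titration for the 1:1 convention)",
               call. = FALSE)
        r <- donor_acceptor_distance(E, r0)
        list(J = J, r0_nm = r0, efficiency = E, r_nm = r,
             conditions = check_forster_conditions(r, r0))
      }, stage)
      tab <- data.frame(J_cm3_L_per_mol = res$fret$J,
                        E = res$fret$efficiency,
                        r_nm = res$fret$r_nm, r0_nm = res$fret$r0_nm)
      utils::write.csv(tab, out_path("fret_table.csv"), row.names = FALSE)
      log <- c(log, sprintf("fret: J = %.4g, R0 = %.3f nm, E = %.4f, r = %.3f nm",
                            res$fret$J, res$fret$r0_nm, res$fret$efficiency,
                            res$fret$r_nm))
    }

    if (stage == "mst") {
      if (is.null(inp$dose_response))
        stop("stage 'mst': no dose-response table (dependency: synth stage or inputs$dose_response)",
             call. = FALSE)
      res$mst <- collect({
        dr <- read_dose_response(inp$dose_response)
        fit_kd(dr$dose_molar, dr$response, A_total = config$A_total)
      }, stage)
      tab <- data.frame(kd_nM = res$mst$kd * 1e9,
                        kd_se_nM = res$mst$kd_se * 1e9,
                        baseline = res$mst$baseline,
                        amplitude = res$mst$amplitude)
      utils::write.csv(tab, out_path("mst_table.csv"), row.names = FALSE)
      log <- c(log, sprintf("mst: Kd = %.4g +/- %.2g nM",
                            res$mst$kd * 1e9, res$mst$kd_se * 1e9))
    }

    if (stage == "cd") {
      if (is.null(inp$cd_spectrum))
        stop("stage 'cd': no CD trace (inputs$cd_spectrum)", call. = FALSE)
      res$cd <- collect({
        tr <- read_spectrum(inp$cd_spectrum, kind = "cd")
        mre(tr, config$protein)
      }, stage)
      write_spectrum(res$cd, out_path("mre_trace.csv"))
      log <- c(log, "cd: converted observed ellipticity to MRE")
    }

    if (stage == "eem") {
      if (is.null(inp$eem))
        stop("stage 'eem': no EEM matrix (dependency: synth stage or inputs$eem)",
             call. = FALSE)
      res$eem <- collect(eem_peaks(read_eem(inp$eem)), stage)
      utils::write.csv(res$eem, out_path("eem_peaks.csv"), row.names = FALSE)
      log <- c(log, sprintf("eem: %d peaks/ridges found", nrow(res$eem)))
    }

    if (stage == "ans") {
      if (is.null(inp$ans_reference))
        stop("stage 'ans': no ANS titration (dependency: synth stage or inputs$ans_reference)",
             call. = FALSE)
      res$ans <- collect({
        read_xy <- function(p) {
          m <- parse_numeric_table(p, 2L)
          hydrophobicity_slope(m[, 1], m[, 2])
        }
        ref <- read_xy(inp$ans_reference)
        out <- list(reference = ref)
        if (!is.null(inp$ans_treated)) {
          out$treated <- read_xy(inp$ans_treated)
          out$drop_percent <- hydrophobicity_change_percent(ref, out$treated)
        }
        out
      }, stage)
      tab <- data.frame(
        system = names(res$ans)[vapply(res$ans, inherits, logical(1),
                                       "hydrophobicity_fit")],
        s0 = vapply(Filter(function(x) inherits(x, "hydrophobicity_fit"),
                           res$ans), `[[`, numeric(1), "s0"),
        r_squared = vapply(Filter(function(x) inherits(x, "hydrophobicity_fit"),
                                  res$ans), `[[`, numeric(1), "r_squared"))
      utils::write.csv(tab, out_path("ans_table.csv"), row.names = FALSE)
      log <- c(log, sprintf("ans: %d system(s)%s", nrow(tab),
                            if (!is.null(res$ans$drop_percent))
                              sprintf("; S0 drop %.1f%%", res$ans$drop_percent)
                            else ""))
    }
  }

  if (length(warns)) log <- c(log, paste("warning:", warns))
  writeLines(log, out_path("run_log.txt"))
  res$warnings <- warns
  res$log <- log
  class(res) <- "pipeline_run"
  invisible(res)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("pipeline run\n")
  cat(paste(" ", x$log, collapse = "\n"), "\n")
  invisible(x)
}
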