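# Shared fixtures: everything is generated in code at test time.

table_params <- function() deb_params()

zero_noise <- function() {
  noise_model(cv = c(X = 0, SC = 0, SN = 0), floor = c(X = 0, SC = 0, SN = 0))
}

growth_scenarios <- function() limitation_scenarios()[1:6]

# a mid-exponential culture state under substrate excess
midlog_state <- function(params = table_params(), MV = 1e-3) {
  br <- balanced_reserves(params)
  culture_state(SC = grams_to_cmol(4, "glucose"),
                SN = grams_to_cmol(0.5, "NH4Cl"),
                mEc = br[["mEc"]], mEn = br[["mEn"]], MV = MV)
}

FLUX_NAMES <- c("jEcA", "jEnA", "jEcC", "jEnC", "jEcG", "jEnG", "jG", "r",
                "jEcR", "jEnR", "jVMc", "jVMn", "jVM", "JNH3")

# total carbon and nitrogen along a trajectory (per liter of medium)
element_totals <- function(tr, params) {
  V <- attr(tr, "volume")
  list(C = tr$SC_cmol_L * V + (1 + tr$mEc) * tr$MV_cmol + tr$dissC,
       N = tr$SN_mol_L * V + (params$nNV + tr$mEn) * tr$MV_cmol + tr$dissN)
}
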