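# Shared vocabulary of the simulation model (loaded before all other files)

# event-history flags tracked on the state
.t1d_events <- c("mi", "stroke", "chf", "pci", "cabg", "angina", "pvd",
                 "amputation", "hypoglycaemia", "hyperglycaemia", "esrd")

# the 14 event equations: 13 endpoints plus all-cause death
.t1d_event_equations <- c("nonfatal_mi", "fatal_mi", "nonfatal_stroke",
                          "fatal_stroke", "chf", "angina", "pvd",
                          "amputation", "hypoglycaemia", "hyperglycaemia",
                          "esrd", "pci", "cabg", "death")

# which history flag each event equation feeds (death feeds none)
.t1d_event_flag <- c(nonfatal_mi = "mi", fatal_mi = "mi",
                     nonfatal_stroke = "stroke", fatal_stroke = "stroke",
                     chf = "chf", angina = "angina", pvd = "pvd",
                     amputation = "amputation", hypoglycaemia = "hypoglycaemia",
                     hyperglycaemia = "hyperglycaemia", esrd = "esrd",
                     pci = "pci", cabg = "cabg", death = NA_character_)

# events that terminate the simulation when drawn
.t1d_fatal_default <- c("death", "fatal_mi", "fatal_stroke")

.t1d_continuous_targets <- c("hba1c", "bmi", "sbp", "tg", "hdl", "ldl", "egfr")
.t1d_binary_targets <- c("current_smoker", "microalbuminuria", "macroalbuminuria")
.t1d_progression_targets <- c(.t1d_continuous_targets, .t1d_binary_targets)
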