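# Structural template for an acute-care mobile integrated health program's
# cost model: the standard fixed/variable cost taxonomy with PERT
# (min / most-likely / max) uncertainty on every line, ~800 annual visits,
# 60% basic / 40% advanced complexity mix.
#
# SYNTHETIC PLACEHOLDER DOLLAR RANGES: the triples below are public
# order-of-magnitude salary/equipment figures, not any program's accounts.
# Use calibrate_config() to scale this template so that its simulated
# medians match target per-visit costs.
visit_mix:
  annual_visits: {min: 700, mode: 800, max: 900}
  prop_basic: 0.60
  prop_advanced: 0.40
simulation:
  iterations: 1000
  interval_level: 0.90
  seed: 1
  pert_shape: 4
allocation_weights: {basic: 1.0, advanced: 1.0}
elements:
  - id: personnel_paramedics
    label: "Paramedic salaries with fringe (6.5 full-time effort)"
    classification: fixed
    basis: per_period
    applicability: all
    reimbursable: false
    pert: {min: 520000, mode: 585000, max: 650000}
  - id: personnel_administrator
    label: "Program administrator salary with fringe (1.0 FTE)"
    classification: fixed
    basis: per_period
    applicability: all
    reimbursable: false
    pert: {min: 70000, mode: 85000, max: 100000}
  - id: personnel_physician
    label: "Physician medical direction with fringe (0.5 FTE)"
    classification: fixed
    basis: per_period
    applicability: all
    reimbursable: false
    pert: {min: 90000, mode: 110000, max: 130000}
  - id: administrative
    label: "Administrative costs: state license fees, paramedic certification fees, continuing education courses, operational software"
    classification: fixed
    basis: per_period
    applicability: all
    reimbursable: false
    pert: {min: 15000, mode: 25000, max: 40000}
  - id: equipment
    label: "Non-disposable clinical equipment (annualized): cardiac monitors, point-of-care blood machine, laptop computers, portable printers, radios, WIFI hotspot, clinical software"
    classification: fixed
    basis: per_period
    applicability: all
    reimbursable: false
    pert: {min: 30000, mode: 45000, max: 70000}
  - id: fuel
    label: "Fuel (annual)"
    classification: variable
    basis: per_period
    applicability: all
    reimbursable: false
    pert: {min: 8000, mode: 10000, max: 14000}
  - id: vehicle_maintenance
    label: "Vehicle maintenance (annual)"
    classification: variable
    basis: per_period
    applicability: all
    reimbursable: false
    pert: {min: 4000, mode: 6000, max: 9000}
  - id: laboratory_analysis
    label: "Laboratory analysis (expected per-visit cost)"
    classification: variable
    basis: per_visit
    applicability: all
    reimbursable: true
    pert: {min: 40, mode: 60, max: 90}
  - id: radiology
    label: "Radiology studies and interpretation (expected per-visit cost)"
    classification: variable
    basis: per_visit
    applicability: all
    reimbursable: true
    pert: {min: 90, mode: 150, max: 250}
  - id: medications_supplies_basic
    label: "Oral medications, prescriptions and clinical supplies per basic visit"
    classification: variable
    basis: per_visit
    applicability: basic_only
    reimbursable: false
    pert: {min: 15, mode: 30, max: 60}
  - id: iv_therapy_advanced
    label: "Intravenous medications and fluids with administration supplies per advanced visit"
    classification: variable
    basis: per_visit
    applicability: advanced_only
    reimbursable: false
    pert: {min: 60, mode: 120, max: 220}
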