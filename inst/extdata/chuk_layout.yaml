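# Reference layout for a CHUK-style intraoperative anesthesia chart.
# All coordinates are pixels in the dewarped control frame (origin top-left,
# y downward). Section-relative fields (bp_legend, physio_rows y_band) are in
# the local frame of their section crop.
reference_width: 1000
reference_height: 700
landmarks:
  Time: {x: 40.0, y: 30.0}
  Total: {x: 960.0, y: 30.0}
  Procedure Details: {x: 40.0, y: 670.0}
  Patient Position: {x: 960.0, y: 670.0}
sections:
  medications: {x: 60.0, y: 55.0, width: 540.0, height: 90.0}
  volatile_agents: {x: 620.0, y: 55.0, width: 340.0, height: 40.0}
  iv_fluids: {x: 620.0, y: 100.0, width: 340.0, height: 40.0}
  transfusion: {x: 620.0, y: 145.0, width: 340.0, height: 40.0}
  blood_pressure: {x: 60.0, y: 160.0, width: 540.0, height: 260.0}
  physiology: {x: 60.0, y: 440.0, width: 540.0, height: 180.0}
  checkboxes: {x: 620.0, y: 200.0, width: 340.0, height: 420.0}
# approximate regions of the mmHg legend markers, blood-pressure-section frame
bp_legend:
  '200': {x: 30.0, y: 40.0, width: 51.0, height: 21.0}
  '30': {x: 21.0, y: 210.0, width: 33.0, height: 21.0}
# physiology-section frame; value_range / max_step in row units per epoch.
# respiratory_rate shares the written tidal-volume line ("450x12"); its band
# here is an unused placeholder kept disjoint, its ranges apply after the
# X-split.
physio_rows:
- name: SpO2
  y_band: [5.0, 40.0]
  value_range: [75.0, 100.0]
  digit_count_range: [2, 3]
  max_step: 5.0
- name: EtCO2
  y_band: [45.0, 80.0]
  value_range: [15.0, 60.0]
  digit_count_range: [2, 2]
  max_step: 10.0
- name: FiO2
  y_band: [85.0, 120.0]
  value_range: [21.0, 100.0]
  digit_count_range: [2, 3]
  max_step: 20.0
- name: tidal_volume
  y_band: [125.0, 160.0]
  value_range: [200.0, 800.0]
  digit_count_range: [4, 6]
  max_step: 150.0
- name: respiratory_rate
  y_band: [165.0, 178.0]
  value_range: [5.0, 40.0]
  digit_count_range: [2, 2]
  max_step: 5.0
checkbox_columns:
- name: Patient Safety
  labels: [Eye Protection, Warming, TED Stockings, Safety Checklist]
- name: Patient Position
  labels: [Supine, Prone, Lateral, Lithotomy]
- name: Airway
  labels: [ETT, LMA, Face Mask, Tracheostomy]
- name: Monitoring
  labels: [ECG, NIBP, SpO2 Probe, Capnography]
expected_checkbox_count: 16
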