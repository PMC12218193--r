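# Example run configuration for a German ESS-style climate-change survey
# export (delimited text). The reader itself is survey-agnostic: all
# survey-specific column names and codes live here.
columns:
  wave: essround
  weight: anweight
  party: prtclde        # prtcl[e/f/g]de depending on the round
  closeness: prtdgcl
  items: [wrclmch, ccnthum]
likert:
  levels: [1, 2, 3, 4, 5]   # mapped to 0, 0.25, 0.5, 0.75, 1
  missing: [6, 7, 8, 9]     # don't know / refusal / no answer
filters:                    # applied in this order, counts ledgered
  invalid_item_response: true
  disqualifying_answer:
    item: ccnthum
    codes: [55]             # "climate is not changing"
  other_party: true
  party_refusal: true
party_map:
  "1": CDU/CSU
  "2": SPD
  "3": Die Linke
  "4": Buendnis 90/Die Gruenen
  "5": FDP
  "6": AfD
closeness:
  no_preference_codes: [66]  # no party named -> nonpartisan "None"
  refusal_codes: [77, 88, 99]
  not_close_codes: [4]       # "not at all" close -> "None"
lens:
  mode: instantaneous
  ridge_epsilon: 1.0e-6
  min_group_size: 3
baseline: "8"
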