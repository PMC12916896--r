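# Example column mapping for ingesting a locally deposited behavioural
# table with reproduce_osf(). Keys are the package's canonical names;
# values are the columns (or choice labels) used in the deposited file.
participant: subject_id
trial: trial_number
choice: response
v_internal: value_internal
v_external: value_external
v_accept: value_accept
cost: cumulative_cost
label_internal: internal_exploration
label_external: external_exploration
label_accept: accept
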