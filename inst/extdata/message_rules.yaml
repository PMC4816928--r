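- rule_id: ineligible_foodswitch_link
  trigger: first eligibility check failed
  anchor: screening
  offsets: 0
  monthly_after: no
  channel: in-app
  repeat_cap: 1.0
- rule_id: registration_reminder
  trigger: registration or baseline questionnaire not completed
  anchor: consent
  offsets:
  - 2
  - 9
  - 16
  - 23
  - 30
  monthly_after: yes
  channel: push
  repeat_cap: Inf
- rule_id: runin_under_threshold
  trigger: list submitted in week 1 with running total below the run-in threshold
  anchor: list
  offsets: 0
  monthly_after: no
  channel: in-app
  repeat_cap: Inf
- rule_id: list_sent_success
  trigger: list transmitted with week-1 total at or above the run-in threshold
  anchor: list
  offsets: 0
  monthly_after: no
  channel: in-app
  repeat_cap: Inf
- rule_id: baseline_recording_reminder
  trigger: no product list sent since the beginning of week 1
  anchor: registration
  offsets:
  - 3
  - 5
  monthly_after: no
  channel: push
  repeat_cap: 2.0
- rule_id: intervention_keep_recording
  trigger: no new product list during the intervention phase
  anchor: last_list_or_intervention
  offsets:
  - 4
  - 6
  - 9
  - 12
  - 18
  - 24
  monthly_after: no
  channel: push
  repeat_cap: 28.0
- rule_id: trial_ending_soon
  trigger: day 26 of the intervention phase reached
  anchor: intervention
  offsets: 26
  monthly_after: no
  channel: push
  repeat_cap: 1.0
- rule_id: followup_request
  trigger: day 28 of the intervention phase reached
  anchor: intervention
  offsets: 28
  monthly_after: no
  channel: in-app
  repeat_cap: 1.0
- rule_id: followup_reminder
  trigger: follow-up questionnaire not completed
  anchor: intervention_end
  offsets:
  - 6
  - 12
  - 18
  - 24
  - 30
  monthly_after: no
  channel: push
  repeat_cap: 5.0
- rule_id: trial_completed
  trigger: follow-up questionnaire completed
  anchor: followup
  offsets: 0
  monthly_after: no
  channel: in-app
  repeat_cap: 1.0
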