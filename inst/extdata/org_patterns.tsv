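language_pattern	lived in
language_pattern	lives in
language_pattern	lived at
language_pattern	stayed at
language_pattern	come from
language_pattern	comes from
language_pattern	came from
language_pattern	grew up in
language_pattern	attends
language_pattern	attended
language_pattern	enrolled at
language_pattern	works at
language_pattern	worked at
language_pattern	admitted to
org_type	school
org_type	high school
org_type	elementary school
org_type	church
org_type	parish
org_type	hospital
org_type	clinic
org_type	foster home
org_type	group home
org_type	nursing home
org_type	retirement home
org_type	shelter
org_type	orphanage
org_type	daycare
org_type	military base
org_type	regiment
org_type	battalion
org_type	aid society
org_type	support center
org_type	support centre
org_type	community center
org_type	community centre
target_population	youth
target_population	women
target_population	seniors
target_population	children
target_population	veterans
target_population	teens
target_population	elders
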