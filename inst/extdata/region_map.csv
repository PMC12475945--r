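code,region
HN,head/neck
FC,face
CH,chest
AB,abdomen
UE,extremities
LE,extremities
OT,other
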