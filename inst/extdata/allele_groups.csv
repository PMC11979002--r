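pattern,group
^DQB1\*02,DQ2
^DQB1\*03:02,DQ8
^DQB1\*03,DQ7
^DQB1\*04,DQ4
^DQB1\*05,DQ5
^DQB1\*06,DQ6
^DRB1,DR
^DPB1,DP
^A\*,A
^B\*,B
^C\*,C
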