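criterion,r_x,r_y,expected_difference
C01,0.45,0.15,TRUE
C02,0.50,0.20,TRUE
C03,-0.35,-0.05,TRUE
C04,0.40,0.12,TRUE
C05,0.25,-0.02,TRUE
C06,0.34,0.32,FALSE
C07,-0.01,-0.01,FALSE
C08,-0.18,-0.21,FALSE
C09,-0.21,-0.18,FALSE
C10,-0.10,-0.11,FALSE
C11,0.23,0.24,FALSE
C12,-0.05,-0.06,FALSE
C13,0.33,0.36,FALSE
C14,-0.15,-0.13,FALSE
C15,0.03,0.06,FALSE
C16,-0.15,-0.18,FALSE
C17,-0.11,-0.10,FALSE
C18,0.21,0.21,FALSE
C19,-0.19,-0.16,FALSE
C20,0.02,0.01,FALSE
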