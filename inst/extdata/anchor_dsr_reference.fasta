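>DSR_REF synthetic DsrB-like anchor reference [synthetic]
QRIAIPYFPPRIGNRIDYIYGHRFQAHMHGGEVGEFVAVRTPWLINFRQSYFMWVFRPVY
KVQAVWKFDDERNREPKSQRWHKFETSIKWWMQLHVESGVYWGHTREEVIFWFMRGPQEF
YWEVHKQHMKKHQAEWQRVTGHSHSALGTCPFLHTCGDWEVLTPTDVVPCLVLAICGKKA
PFIQEYGQWRSAKQVEWTMSDTADESSFTCSHIHYCPYCWLERFCPGMHLQFSESDETEC
PFCYWCLTHCALSRKLGEVPHVAQLNFAGYPDFYSTVYGRTRQMQRDNNPGLWLLFIKWF
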