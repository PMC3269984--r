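>MIR156a
UGACAGAAGAGAGGGAGCAC
>MIR156b
UGACAGAAGAGAGUGAGCAC
>MIR160
UGCCUGGCUCCUUGUAUGCCA
>MIR166a
UCGGACCAGGCUUCAUUCCUC
>MIR166b
UCGGACCAGGCUUCAUUCCCC
>MIR167a
UGAAGCUGCCAGCAUGAUCUA
>MIR167b
UGAAGCUGCCAGCAUGAUCUA
>MIR167c
UGAAGCUGCCAGCAUGAUCUG
>MIR172a
AGAAUCUUGAUGAUGCUGCAU
>MIR172b
AGAAUCUUGAUGAUGCUGCAU
>MIR396
UUCCACAGCUUUCUUGAACUG
>MIR397
CCAUUGAGUGCAGCGUUGAUG
>MIR408
CUGCACUGCCUCUUCCCUGGC
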