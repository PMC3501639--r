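>PRI_01
ACGTTACGGATCCATTAGCAATCGATCGATTAGCCATAAC
>PRI_02
ACGTTACGGATCCATTAGCAATCGATCGATTAGCCATAAC
>PRI_03
ACGTTACGGATCTATTAGCAATCGATCGATTAGCCATAAC
>PRI_04
ACGTTACGGATCCATTAGCAATCGATCGATTAGCTATAAC
>PRI_05
ACGTAACGGATCCATTAGCAATCGATCGATTAGCCATAAC
>PRI_06
ACGTTACGGATCCATTAGCAATCGATCGCTTAGCCATAAC
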