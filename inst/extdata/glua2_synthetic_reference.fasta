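>GluA2_synthetic_reference synthetic scaffold on mature rat GluA2 numbering (not the UniProt P19491 sequence); documented residues planted at annotated positions
LPTEDKTTPSHAVITAPKKGVEEGALSGAFLANYNLAIVQSPRKSGDVASLRISKICTSD
TFALGDSISLYGLYVRIGNVESPDAKSDNYTKEQLAIFWEAQILEEIANSSTLNIPTTLL
LKVDNATQGRTDLFAYRDIVSAKGEFVNEQFRMDINAADKRDSEILPPPEVRYSQVGRQG
TELEGRDTRKGNLKVFGQFPGTTRKESLIEHENLQVFADARPTMGGLYEGLIIIAAVPTS
VEEKDEKIFLETGGESLKAMFGCDNLPGALGHAKPFGPKTLHSCYKIAMFVQKEGFGFFR
LVAEGPACITMMGWKLNLATNVVLSGGQSSVATDNQACDVQQSYANHKRLLVSFCDMPDM
ETAGQGVFGSNPTVRATCTSISLLSDQEDAIFLLEERTIERKTVSQVSVFINEDSEAMPL
IDISHPGANTIGIILTASGADASHAVLEPYEQDNHSVATDKFVWVVGEGEKFEGGINPSS
CSAMRATDPAILHGFSEQYASERFTVYNDIKIDGLGWFIVLTAYGIVKSAAAITLDAISE
RSNRVATMKGLKSKRGTRGNRMILIALKLRVSLAKAPAQGAIGNPPMLAFDSFPAPNATP
IAVNRAQEEYDGNKSSYTANLAAFMVDPKNLTKPIKYRFGSDILSFDNSYCIGSTELTGD
SAKGSGGSNAIEESIRDQYMMAGEYHMKLAGTYNLHHKLDELLEDLHGVIMMKKMVRNNV
ADFLTSRKEKGYKHSMCAGQASIAALSRVLCRWERETTVVALPESLYADIPQYVTLDSVI
LPWKDPAVVLDFKNGRKLRGMYALLYDHFKGHRNKLIPNETASMLQRDSDESRAIANGVG
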