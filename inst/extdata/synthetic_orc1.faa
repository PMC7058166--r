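>Hsap
ENLTDGFQIWRWRGPNYDSWGNFLAVVFRWIFFPAPLWGNAPHDSENNYWETAHQYNWNRKEMWQDFDQDWLWDNYWDML
MYWNYGLYCNRIHRESKWIDEHPGLCWGTCRCRMIIHDVWHWYCYRDAMAVLVCHNSKMKGTPEGSNVEQ
>T012
KNYWNWFQIRVNRGRGYDDCHNWLAVWWQTINWPKCLQQNAPVSWENNYPETAHDVNWARKVFWQKFDQDWLWDTYEDST
MGENGGLYFWRIADLLKHHIEHPGLCWDTCRTRYAIGDQARWYCYRWRLFVLVCVNSWMKAAPELSNVGD
>T008
THCTVIFQILRIYGPNTYSPCNFMCGVAQWEFFFAHLQGDAPHWSHYHQWHRYWQPTWNRKEMRVDNDQLWLWHNYWDMA
KYAWAKRYMNRIHREKKIIDEHPMLCLGTCRCPHFVANYHHWKMYRIARVVLVCHNSKMKSTDCGSTVEQ
>T002
DNLWDGFQIERWQGRVYDRWQNFHAEVFVFIGPNDMNWGGAPHDEGCFTWNAAHSYNWWRRYMNSGADEVWLPLNCSWFG
DVWCYGSTCNRMHREPIWIDPHPRLCFRTPRCRMICHQVWHGYCLGSAMIIGVCHNSKITACGKEVNVLQ
>T001
SNGKDGLQDWRRTGPNYVSPGHFLMYGFQTMFFPVPLWGNAPHASENPLCEHAHQYGWNRYEYHEDFDQCTLWENHNGDL
CDEAYGQYCNRIHQCSKGIDEHPGLIWGTCRCRMIIHDVWHWACHSDGCAVNVMHNSKMKNHCEGTNVEQ
>T006
EPARPTYMHWVVRGVNRVTWHNFRAVNFRWIFDPAPHWYMAPHVSEQNYWEFNHQSNWNRVTMTQNFFQPVLWFNVWMCH
YERNFGLACNGICQGSRWIACGDGLCWITKPRRMECHLVFVEVDCRDKMAMLVCRNPKMKVQPEVAMVLQ
>T003
ESLTDAFQRNYSRGKALDEWGNIPCFIFRMYFFCAPLWWNAPIYYENGYWERAHEPNWARKEMWMDFDQKALWDNYMMIW
SHWVYWANCNRAKTESKWINEHGGDCWGHCRGRMTIYGQWFVYRYEDAMAVLNCFNWLEKGTPEQSNPEQ
>T005
YNLTYGFCIWKWRGGLYDSWGNTLAVMGWHFWMPAPSVGNADMSRENRYEEQTHTYGWFFDSMNQDLDQDWLWDMWIDML
MTRNYGLYWNTPHIESKWNDEVNGTCHGTCRRLLKIKDVWHWYEYRDAMLVLVCHNSQMKGTPEGNTEEF
>T011
ESMRRLFQIRRYRGPAHDSWCCRNKVVFLGWSFPRPTQGMFQHDSENNEVETAHMYRWLLKWMWQDFDFNYTWDNYWDEE
TYWNSGLGRNELPRYHTWIDEHPDLCKSTPLGRADPHDGWHWSKLMCAFALDVCLNIKDKWTPEGSNVLD
>T013
ECLTDRFWISHEKDKNKDSWGMDLAVVSRWIKEPAPFWAMAPHDLENYYMNTKKVGNWNRDETCQDMTQQWLIDNYMMMP
MCWDYVLYCNMYERESHWILLHPGLFSGTCNPCMEITNVGGPYCYSDAMAVLNHHDGKMKGQYLGSMQEQ
>T009
ENTKDGFQAWRWVQPWEDSFGGFLLVTFRKIFGPGRLWECVWHESENNYWEQAFQMRWDRKEMKQDFAQDWWMDNQHDID
MYWKQDYYCNRIQSASKWIYEHMGLCWGTCRCRMIWHDICSWQCLAAAMLVLVCHLSKMSGEPIFVNAHK
>T007
MCEFCELTAWRWRGPYCDSWYMEVCVGLRGICFPLYLCGAWPHDNENQYWWTAPWYNQNLSEMWQDFDCRWLRLAYWDML
MQWNAGSYGNRICGESVWIDEHPGLCWGCCRCRNRIHDFNHWYCYRDAMDVLTRHNSKKKLTPQGSLVHQ
>T004
GNLTDGFYAHYWCGPNSDPNGWFLAVNFQSTFALAHLGGNAPHMSEDHLYETAHWSPPGRKEMRHDFAQDGLWDNYCDML
SHWNYGLYDNMMSREDFWDVEHLGKKWGTCRCRMCIHTYWAWYKYRDADAVLVCHNSKMKKMPEESIVTS
>T010
ECLQQGGQIQRWRCPVYNSWQNCLQVPFRWGWTELGLKGDAPHAMENNYSVTWNIDNWDHKEYIVMFNGKWLHDNQNRFL
NMWWKGFPIWRIHRHVKWIDEHPGLCWVTCRCRMWESDCWHWYIYMDYMDVLVCHNHKMKFTPRWSNVSS
>T014
EPLIEKFYICRWFGMVYWSWSIELANVKWWIFFPFYLWGNAPQDSEENYREFEHFDSGYRKEMWQNYVENFVWINYADWL
AYCNYDLLCNRISREHKAFYEHPCLCCGTCDYGVIIESRWHSRCDEDYGVEQFCHNSKQSGTDECHRVDQ
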