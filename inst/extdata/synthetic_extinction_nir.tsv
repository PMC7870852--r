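# log_base: 10
wavelength_nm	HbO2	HHb	oxCCO
780	0.55007123262221924	1.6660734832375488	0.94433459173049039
782	0.56509841726016385	1.6042756645676097	1.0068692714613867
784	0.58013509130602148	1.5406607165779658	1.0725468264600289
786	0.59518422447232544	1.4758886214879274	1.1411405649719768
788	0.61024959221391117	1.410596865917447	1.2123687418086928
790	0.62533595300996392	1.3453905949539082	1.2858941110729645
792	0.64044925180514378	1.2808340784865224	1.3613245303315482
794	0.65559684961258191	1.2174436301280709	1.4382146908787368
796	0.67078777789961119	1.1556820655064863	1.5160690240201216
798	0.68603301460247557	1.0959547337737563	1.5943458050432282
800	0.70134577643547957	1.0386071058743078	1.6724624454460189
802	0.71674181958550309	0.98392385720715314	1.749801930945414
804	0.73223973796036912	0.93212934224881705	1.8257203288055288
806	0.747861244975492	0.88338932555274163	1.8995552542344585
808	0.76363142154993158	0.8378138079922558	1.9706351531892248
810	0.77957890972218358	0.7954607694676239	2.0382892291090702
812	0.79573602831878176	0.75634063948592867	2.1018578150437426
814	0.81213878469097112	0.72042130464970577	2.160702971448043
816	0.82882675498738667	0.68763346648273727	2.2142190745349777
818	0.84584280508471732	0.65787617328809511	2.2618431512947033
820	0.86323262548317725	0.63102236483056584	2.3030647156512507
822	0.88104405649062001	0.60692428743213211	2.3374348660467832
824	0.89932618511082507	0.5854186584099591	2.3645744180422987
826	0.91812820236817694	0.56633148154823076	2.3841808660485033
828	0.93749801936771993	0.54948243843538602	2.3960339955141912
830	0.95748065207626487	0.53468880309233402	2.3999999999999999
832	0.97811639830839958	0.52176884858613226	2.3960339955141912
834	0.99943884521117632	0.51054473365029429	2.3841808660485033
836	1.0214727609728342	0.5008448742679974	2.3645744180422987
838	1.0442319396705306	0.49250581943316019	2.3374348660467832
840	1.0677170821176158	0.48537366175526347	2.3030647156512507
842	1.0919138071845438	0.47930502222197469	2.2618431512947033
844	1.116790896244394	0.47416765439937419	2.2142190745349777
846	1.1422988770946698	0.46984071684473216	2.160702971448043
848	1.1683690520462846	0.46621476381037719	2.1018578150437426
850	1.1949130672075112	0.46319150375172147	2.0382892291090702
852	1.2218231060107621	0.46068337306199669	1.9706351531892248
854	1.2489727698122197	0.4586129691870689	1.8995552542344585
856	1.2762186824534876	0.45691238315855048	1.8257203288055288
858	1.3034028249737226	0.45552246692890008	1.749801930945414
860	1.3303555725886889	0.45439206596986026	1.6724624454460189
862	1.3568993703637431	0.45347724263639666	1.5943458050432282
864	1.3828529487247063	0.45274051099011814	1.5160690240201216
866	1.4080359472415529	0.45215009926376898	1.4382146908787368
868	1.4322737871479643	0.45167925203562848	1.3613245303315482
870	1.4554026118244312	0.45130558053611547	1.2858941110729645
872	1.4772741016516215	0.45101046636262243	1.2123687418086928
874	1.4977599664487622	0.45077852123940754	1.1411405649719768
876	1.5167559257869274	0.45059710331234731	1.0725468264600289
878	1.5341850047979377	0.4504558887822025	1.0068692714613867
880	1.55	0.45034649641208874	0.94433459173049039
882	1.5641850047979375	0.45026216154539517	0.88511582903309738
884	1.5767559257869275	0.45019745568653868	0.82933462328008822
886	1.5877599664487623	0.45014804737557823	0.77706418224514273
888	1.5972741016516216	0.45011049997790431	0.72833284270297138
890	1.6054026118244311	0.45008210206486915	0.68312809014671438
892	1.6122737871479644	0.45006072623821519	0.64140090562295926
894	1.6180359472415531	0.45004471251393463	0.60307031322354931
896	1.6228529487247061	0.45003277269895503	0.56802800987163815
898	1.6268993703637431	0.45002391254163965	0.53614296965505892
900	1.6303555725886891	0.45001736879464527	0.50726592748428279
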